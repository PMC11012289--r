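# Plain-text persistence of campaign artifacts. Fingerprints are stored as
# JSON lines (one sparse index list per compound); everything else is CSV.

#' Write a synthetic campaign to disk
#'
#' Writes `library.csv` (compound records without fingerprints),
#' `fingerprints.jsonl` (one `{"compound_id": ..., "fp_bits": [...]}` object
#' per line) and `truth.json` (class fractions, seed, generator parameters).
#'
#' @param campaign A [generate_library()] campaign.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_campaign <- function(campaign, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lib <- select(campaign$library, -"fp_bits")
  readr::write_csv(lib, file.path(dir, "library.csv"))
  lines <- vapply(seq_len(nrow(campaign$library)), function(i) {
    jsonlite::toJSON(list(compound_id = campaign$library$compound_id[i],
                          fp_bits = campaign$library$fp_bits[[i]]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, file.path(dir, "fingerprints.jsonl"))
  jsonlite::write_json(
    list(class_fractions = as.list(campaign$class_fractions),
         seed = campaign$seed, params = campaign$params),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a synthetic campaign written by [write_campaign()]
#'
#' @param dir Directory holding the campaign files.
#' @return A `campaign_truth` object.
#' @export
read_campaign <- function(dir) {
  lib <- readr::read_csv(file.path(dir, "library.csv"),
                         show_col_types = FALSE,
                         col_types = readr::cols(compound_id = "c",
                                                 cluster_id = "c",
                                                 smiles = "c"))
  lib$mech_class <- factor(lib$mech_class, levels = MECH_CLASSES)
  fps <- lapply(readLines(file.path(dir, "fingerprints.jsonl")),
                jsonlite::fromJSON)
  fp <- tibble(compound_id = vapply(fps, `[[`, character(1), "compound_id"),
               fp_bits = lapply(fps, function(x) as.integer(x$fp_bits)))
  lib <- left_join(lib, fp, by = "compound_id")
  truth <- jsonlite::fromJSON(file.path(dir, "truth.json"))
  structure(
    list(library = as_tibble(lib),
         class_fractions = unlist(truth$class_fractions),
         seed = truth$seed, params = truth$params),
    class = "campaign_truth"
  )
}

#' Write / read plate well signals
#'
#' @param plates Well-signal tibble.
#' @param path CSV path.
#' @return The tibble (readers) or the path, invisibly (writers).
#' @export
write_plate_csv <- function(plates, path) {
  readr::write_csv(plates, path)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(plate_id = "c", well = "c",
                                          role = "c", compound_id = "c"))
}

#' Write / read melt curves
#'
#' Long format: `sample_id`, `replicate`, `temp_C`, `fluorescence`.
#'
#' @param curves Melt-curve tibble.
#' @param path CSV path.
#' @export
write_melt_csv <- function(curves, path) {
  readr::write_csv(curves, path)
  invisible(path)
}

#' @rdname write_melt_csv
#' @export
read_melt_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(sample_id = "c"))
}
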