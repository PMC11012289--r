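# Laplacian-corrected naive Bayes over binary substructure fingerprints --
# the standard HTS model for enriching a primary-active list with likely
# false negatives.

#' Fit a Laplacian-corrected naive Bayes fingerprint model
#'
#' For every feature `f`, with `N_f` compounds carrying it overall and `A_f`
#' of those among the actives, the model stores the log Laplacian-corrected
#' relative density
#' `w_f = ln[(A_f + 1) / ((N_f + 1) * base_rate)]`, where
#' `base_rate = n_active / n_total`. Features carried only by actives get
#' large positive weights; a feature whose active fraction matches the base
#' rate is uninformative (weight near 0 for large counts). Features absent
#' from every compound get no entry.
#'
#' @param fingerprints Tibble with `compound_id` and a list-column `fp_bits`
#'   of integer feature indices.
#' @param active_ids Compound ids labelled active (must be a non-empty proper
#'   subset of the fingerprinted compounds).
#' @return Object of class `bayes_model` with elements `weights` (named by
#'   feature index), `n_total`, `n_active`, `base_rate`.
#' @examples
#' fps <- tibble::tibble(compound_id = c("a", "b", "c"),
#'                       fp_bits = list(c(1L, 2L), 2L, 3L))
#' m <- bayes_fit(fps, "a")
#' tidy(m)
#' @export
bayes_fit <- function(fingerprints, active_ids) {
  n_total <- nrow(fingerprints)
  active <- fingerprints$compound_id %in% active_ids
  n_active <- sum(active)
  if (n_active == 0 || n_active == n_total) {
    abort("`active_ids` must be a non-empty proper subset of the compounds.")
  }
  base_rate <- n_active / n_total
  # a feature is counted once per compound carrying it
  all_bits <- unlist(fingerprints$fp_bits, use.names = FALSE)
  n_f <- table(all_bits)
  act_bits <- unlist(fingerprints$fp_bits[active], use.names = FALSE)
  a_f <- table(factor(act_bits, levels = names(n_f)))
  w <- log((as.numeric(a_f) + 1) / ((as.numeric(n_f) + 1) * base_rate))
  names(w) <- names(n_f)
  structure(
    list(weights = w, n_total = n_total, n_active = n_active,
         base_rate = base_rate),
    class = "bayes_model"
  )
}

#' @export
print.bayes_model <- function(x, ...) {
  cat("<bayes_model> ", length(x$weights), " features, ",
      x$n_active, "/", x$n_total, " active (base rate ",
      signif(x$base_rate, 3), ")\n", sep = "")
  invisible(x)
}

#' @rdname bayes_fit
#' @param x A `bayes_model`.
#' @param ... Unused.
#' @method tidy bayes_model
#' @export
tidy.bayes_model <- function(x, ...) {
  tibble(feature = as.integer(names(x$weights)), weight = unname(x$weights))
}

#' @rdname bayes_fit
#' @method glance bayes_model
#' @export
glance.bayes_model <- function(x, ...) {
  tibble(n_total = x$n_total, n_active = x$n_active,
         base_rate = x$base_rate, n_features = length(x$weights))
}

#' Score fingerprints with a fitted naive Bayes model
#'
#' The score of a compound is the sum of its features' weights; features
#' unknown to the model contribute 0. Scores are additive over disjoint
#' fingerprint unions and any monotone function of them yields the same
#' ranking.
#'
#' @param fingerprints Tibble with `compound_id` and list-column `fp_bits`.
#' @param model A [bayes_fit()] model.
#' @return Tibble with `compound_id` and `score`.
#' @export
bayes_score <- function(fingerprints, model) {
  stopifnot(inherits(model, "bayes_model"))
  feat <- as.integer(names(model$weights))
  wvec <- numeric(max(c(feat, 1L)))
  wvec[feat] <- unname(model$weights)
  n_w <- length(wvec)
  scores <- vapply(fingerprints$fp_bits, function(b) {
    b <- b[b >= 1L & b <= n_w]
    sum(wvec[b])
  }, numeric(1))
  tibble(compound_id = fingerprints$compound_id, score = scores)
}

#' Augment an active list with top-ranked model predictions
#'
#' Takes the `top_n` compounds by model score (ties broken by ascending
#' compound id) and unions them with the already-called actives, mirroring
#' the false-negative guard used after a primary screen.
#'
#' @param scores Tibble with `compound_id` and `score` for the whole library.
#' @param active_ids Ids already called active.
#' @param top_n How many top-ranked compounds to union in (default 500).
#' @return List: `augmented` (sorted union), `top_ids` (the top-`top_n` set),
#'   `n_added` (top-ranked compounds that were not already active).
#' @export
augment_actives <- function(scores, active_ids, top_n = 500) {
  if (top_n > nrow(scores)) abort("`top_n` exceeds the number of scored compounds.")
  top_ids <- character(0)
  if (top_n > 0) {
    ord <- order(-scores$score, scores$compound_id)
    top_ids <- scores$compound_id[ord[seq_len(top_n)]]
  }
  augmented <- sort(union(active_ids, top_ids))
  list(augmented = augmented, top_ids = sort(top_ids),
       n_added = length(setdiff(top_ids, active_ids)))
}
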