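# Evaluation of predicted complex sets: neighbour-affinity matched
# precision/recall/F-measure, co-localization score, and aggregation of
# precomputed pairwise GO semantic similarities.

#' Do a predicted and a reference complex match?
#'
#' Two complexes match when their neighbour affinity
#' `|p ∩ b|^2 / (|p| |b|)` reaches the threshold `omega`; 0.2 is the
#' conventional choice.
#'
#' @param p,b Non-empty character vectors of protein IDs.
#' @param omega Matching threshold in `(0, 1]`.
#' @return `TRUE` or `FALSE`.
#' @export
complexes_match <- function(p, b, omega = 0.2) {
  stopifnot(is.numeric(omega), omega > 0, omega <= 1)
  neighbour_affinity(p, b) >= omega
}

new_evaluation <- function(n_cp, n_p, n_cb, n_b) {
  precision <- n_cp / n_p
  recall <- if (is.na(n_b)) NA_real_ else n_cb / n_b
  structure(
    list(n_matched_predicted = n_cp, n_predicted = n_p,
         n_matched_reference = n_cb, n_reference = n_b,
         precision = precision, recall = recall,
         f_measure = if (is.na(recall)) NA_real_ else {
           f_measure(precision, recall)
         }),
    class = "complex_evaluation"
  )
}

#' Evaluate predicted complexes against a reference set
#'
#' A predicted complex counts as matched (contributing to `N_cp`) if it
#' matches at least one reference complex at affinity `omega`; a reference
#' complex counts as matched (contributing to `N_cb`) if at least one
#' prediction matches it. Then `precision = N_cp / |P|`,
#' `recall = N_cb / |B|`, and the F-measure is their harmonic mean.
#'
#' @param P Predicted [complex_set()] (non-empty).
#' @param B Reference [complex_set()] (non-empty).
#' @param omega Matching threshold, default 0.2.
#' @return A list of class `complex_evaluation` with fields
#'   `n_matched_predicted`, `n_predicted`, `n_matched_reference`,
#'   `n_reference`, `precision`, `recall`, `f_measure`.
#' @export
evaluate_complexes <- function(P, B, omega = 0.2) {
  P <- complex_set(P)
  B <- complex_set(B)
  if (length(P) == 0 || length(B) == 0) {
    stop_noncall("both the predicted and the reference set must be non-empty")
  }
  match_mat <- vapply(unclass(B), function(b) {
    vapply(unclass(P), function(p) complexes_match(p, b, omega), logical(1))
  }, logical(length(P)))
  match_mat <- matrix(match_mat, nrow = length(P), ncol = length(B))
  new_evaluation(sum(rowSums(match_mat) > 0), length(P),
                 sum(colSums(match_mat) > 0), length(B))
}

#' Build an evaluation result from match counts
#'
#' Useful for recomputing precision/recall/F from published counts (e.g. a
#' comparison table reporting `N_cp` and `|P|` per method).
#'
#' @param n_cp Number of predictions matching at least one reference
#'   complex.
#' @param n_p Total number of predictions.
#' @param n_cb Number of reference complexes matched by at least one
#'   prediction (`NA` if unknown).
#' @param n_b Total number of reference complexes (`NA` if unknown).
#' @return A `complex_evaluation` object; `recall` and `f_measure` are `NA`
#'   when the reference counts are unknown.
#' @export
evaluation_from_counts <- function(n_cp, n_p, n_cb = NA, n_b = NA) {
  stopifnot(n_cp >= 0, n_p >= n_cp)
  new_evaluation(n_cp, n_p, n_cb, n_b)
}

#' @export
print.complex_evaluation <- function(x, ...) {
  cat(sprintf("N_cp = %d of |P| = %d, N_cb = %s of |B| = %s\n",
              x$n_matched_predicted, x$n_predicted,
              format(x$n_matched_reference), format(x$n_reference)))
  cat(sprintf("precision = %s  recall = %s  F-measure = %s\n",
              format_pct(x$precision), format_pct(x$recall),
              format_pct(x$f_measure)))
  invisible(x)
}

format_pct <- function(x) {
  if (is.na(x)) return("NA")
  paste0(formatC(round(100 * x, 2), format = "f", digits = 2), "%")
}

#' Harmonic mean of precision and recall
#'
#' `F = 2 p r / (p + r)`, defined as 0 when both are 0.
#'
#' @param precision,recall Values in `[0, 1]`.
#' @return The F-measure in `[0, 1]`.
#' @export
f_measure <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Co-localization score of one complex
#'
#' The maximal proportion of a complex's annotated members that share a
#' single sub-cellular location. Members without localization annotation
#' are excluded from both numerator and denominator; a complex with no
#' annotated member is unscorable and yields `NA`.
#'
#' @param members Non-empty character vector of protein IDs.
#' @param annot A localization table from [read_localization()] (named list
#'   protein -> location labels).
#' @return Score in `[0, 1]`, or `NA_real_` when no member is annotated.
#' @export
colocalization_score <- function(members, annot) {
  members <- unique(as.character(members))
  if (length(members) == 0) stop_noncall("complex must be non-empty")
  locs <- annot[intersect(members, names(annot))]
  locs <- locs[lengths(locs) > 0]
  if (length(locs) == 0) return(NA_real_)
  counts <- table(unlist(lapply(locs, unique), use.names = FALSE))
  max(counts) / length(locs)
}

#' Co-localization score of a complex set
#'
#' Size-weighted aggregate over scorable complexes:
#' `sum_c max_i |V_i(c)| / sum_c |V(c)|`, where `|V(c)|` counts the
#' annotated members of complex c and `|V_i(c)|` those sharing location i.
#' Complexes without annotated members are skipped.
#'
#' @param cs A [complex_set()].
#' @param annot A localization table from [read_localization()].
#' @return Score in `[0, 1]`.
#' @export
colocalization_set_score <- function(cs, annot) {
  cs <- complex_set(cs)
  num <- 0
  den <- 0
  for (members in unclass(cs)) {
    locs <- annot[intersect(unique(members), names(annot))]
    locs <- locs[lengths(locs) > 0]
    if (length(locs) == 0) next
    counts <- table(unlist(lapply(locs, unique), use.names = FALSE))
    num <- num + max(counts)
    den <- den + length(locs)
  }
  if (den == 0) {
    stop_noncall("no complex has localization-annotated members")
  }
  num / den
}

#' Read a pairwise GO similarity table
#'
#' TSV with header columns `protein_a`, `protein_b`, `sim_cc`, `sim_bp`,
#' `sim_mf`: one row per protein pair, carrying precomputed semantic
#' similarities for the cellular component, biological process and
#' molecular function ontologies. The pair is unordered; duplicate rows for
#' a pair keep the first.
#'
#' @param path Path to the TSV file.
#' @return A data frame of class `go_similarity_table`.
#' @export
read_go_similarity <- function(path) {
  if (!file.exists(path)) stop_noncall("GO similarity file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_a", "protein_b", "sim_cc", "sim_bp", "sim_mf")
  if (!all(need %in% names(df))) {
    stop_noncall("GO similarity table must have columns: ",
                 paste(need, collapse = ", "))
  }
  bad <- unlist(df[, c("sim_cc", "sim_bp", "sim_mf")], use.names = FALSE)
  if (any(bad < 0 | bad > 1, na.rm = TRUE)) {
    stop_noncall("GO similarities must lie in [0, 1]")
  }
  df$.key <- pair_key(as.character(df$protein_a), as.character(df$protein_b))
  df <- df[!duplicated(df$.key), ]
  class(df) <- c("go_similarity_table", "data.frame")
  df
}

#' GO semantic similarity score of a complex set
#'
#' Per complex and ontology, the score is the mean pairwise similarity over
#' member pairs present in the table; pairs without an entry are skipped
#' and complexes with no scorable pair are skipped. Per ontology, the set
#' score is the mean over scorable complexes. The result is the geometric
#' mean of the three ontology set scores (cellular component, biological
#' process, molecular function).
#'
#' @param cs A [complex_set()].
#' @param sims A [read_go_similarity()] table (or a data frame with the
#'   same columns).
#' @return Score in `[0, 1]`. The attribute `ontology_scores` carries the
#'   three per-ontology set scores.
#' @export
go_set_score <- function(cs, sims) {
  cs <- complex_set(cs)
  if (is.null(sims$.key)) {
    sims$.key <- pair_key(as.character(sims$protein_a),
                          as.character(sims$protein_b))
  }
  idx <- stats::setNames(seq_len(nrow(sims)), sims$.key)
  onts <- c("sim_cc", "sim_bp", "sim_mf")
  per_complex <- lapply(unclass(cs), function(members) {
    members <- unique(members)
    if (length(members) < 2) return(NULL)
    pairs <- utils::combn(lex_sort(members), 2)
    rows <- idx[pair_key(pairs[1, ], pairs[2, ])]
    rows <- rows[!is.na(rows)]
    if (length(rows) == 0) return(NULL)
    colMeans(sims[rows, onts, drop = FALSE])
  })
  per_complex <- per_complex[!vapply(per_complex, is.null, logical(1))]
  if (length(per_complex) == 0) {
    stop_noncall("no complex has a scorable member pair")
  }
  mat <- do.call(rbind, per_complex)
  ont_scores <- colMeans(mat)
  structure(prod(ont_scores)^(1 / 3), ontology_scores = ont_scores)
}
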