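# Multi-access (polyclave) identification on the induced matrix, with an
# error tolerance and information-gain character selection.

# mismatch bookkeeping for one row against an observation
row_mismatch <- function(matrix, row, observation) {
  ontology <- matrix$characters
  per_char <- matrix$rows[[row]]
  conflicting <- character(0); supporting <- character(0)
  for (ch in names(observation)) {
    v <- observation[[ch]]
    if (is.na(v)) next
    con <- per_char[[ch]]
    if (is.null(con)) next                     # unconstrained => compatible
    if (constraint_allows(con, v, ontology)) supporting <- c(supporting, ch)
    else conflicting <- c(conflicting, ch)
  }
  # multi-character disjunctions: violated only when every disjunct is
  # determinately false; with several occurrences, the most favourable
  # occurrence counts (identification is conservative)
  disj_sets <- matrix$disjunctions[[row]]
  extra <- 0L
  if (length(disj_sets)) {
    violated <- vapply(disj_sets, function(cl) {
      vals <- vapply(cl, function(p) {
        r <- eval_predicate(p, observation[[p$char_id]], ontology)
        if (is.na(r)) NA else r
      }, logical(1))
      all(vals %in% FALSE)
    }, logical(1))
    extra <- sum(violated)
  }
  list(mismatches = length(conflicting) + extra,
       conflicting = conflicting, supporting = supporting)
}

#' Match an observation against an induced matrix
#'
#' The mismatch count of a taxon is the number of observed characters whose
#' value is incompatible with the taxon's constraint; unconstrained
#' characters are always compatible, and a polymorphic taxon accepts any
#' value inside its constraint union (conservative identification).  All
#' taxa with at most `tolerance` mismatches are returned, ranked by
#' mismatch count with alphabetical tie-break.
#'
#' @param matrix a `dk_matrix` (either level).
#' @param observation named list of observed values (`NA` = unknown).
#' @param tolerance non-negative integer.
#' @return an object of class `dk_match`: data.frame `taxon`, `mismatches`,
#'   `conflicting`, `supporting` (comma-separated character lists), with the
#'   tolerance in attribute `"tolerance"`.
#' @examples
#' key <- load_fixture("syagrus_key")
#' m <- induce_matrix(key, "taxon")
#' res <- polyclave_match(m, list(lamina_thickness = 0.2,
#'                                adaxial_minor_veins = "absent",
#'                                mesophyll_minor_veins = "few"), 0)
#' "S. macrocarpa" %in% res$taxon
#' @export
polyclave_match <- function(matrix, observation, tolerance = 0L) {
  stopifnot(is.numeric(tolerance), tolerance >= 0)
  observation <- check_observation(observation, matrix$characters)
  rows <- names(matrix$rows)
  res <- lapply(rows, function(r) row_mismatch(matrix, r, observation))
  tab <- data.frame(
    taxon = rows,
    mismatches = vapply(res, `[[`, numeric(1), "mismatches"),
    conflicting = vapply(res, function(x)
      paste(x$conflicting, collapse = ","), character(1)),
    supporting = vapply(res, function(x)
      paste(x$supporting, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  tab <- tab[tab$mismatches <= tolerance, , drop = FALSE]
  tab <- tab[order(tab$mismatches, tab$taxon, method = "radix"), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, tolerance = tolerance, class = c("dk_match", "data.frame"))
}

# answer classes for one character over a candidate set: list of candidate
# index vectors, one per distinguishable answer
answer_classes <- function(matrix, candidates, char_id) {
  ontology <- matrix$characters
  ch <- ontology[[char_id]]
  cons <- lapply(candidates, function(r) matrix$rows[[r]][[char_id]])
  if (ch$kind == "quantitative") {
    ends <- unlist(lapply(cons, function(con)
      if (is.null(con)) NULL else c(con$intervals$lo, con$intervals$hi)))
    ends <- sort(unique(ends[is.finite(ends)]))
    if (length(ends) == 0L) probes <- 0
    else {
      mids <- if (length(ends) > 1L) (ends[-1] + ends[-length(ends)]) / 2
              else numeric(0)
      probes <- sort(unique(c(ends[1] - 1, ends, mids, ends[length(ends)] + 1)))
    }
    compat <- lapply(probes, function(v)
      which(vapply(cons, function(con)
        is.null(con) || constraint_allows(con, v, ontology), logical(1))))
  } else {
    compat <- lapply(character_states(ch), function(st)
      which(vapply(cons, function(con)
        is.null(con) || constraint_allows(con, st, ontology), logical(1))))
  }
  # degenerate / equivalent answers merge: keep distinct compatibility sets
  keys <- vapply(compat, function(x) paste(x, collapse = ","), character(1))
  compat[!duplicated(keys) & nzchar(keys)]
}

#' Best next character by expected information gain
#'
#' For each unanswered character the answer space is its state list, or for
#' a quantitative character the partition of the line induced by the
#' candidates' constraint endpoints (answers that no candidate can
#' distinguish are merged).  With `C_a` the candidates compatible with
#' answer `a` and `p(a) = |C_a| / sum |C_a'|`, the expected gain is
#' `log2 |C| - sum_a p(a) log2 |C_a|` bits; the arg-max character is
#' returned, ties broken by `char_id`.
#'
#' @param matrix a `dk_matrix`.
#' @param candidates row names still in play (at least 2).
#' @param answered character ids already answered (excluded).
#' @return list with `character` (id or `NA` if nothing informative),
#'   `gain` (bits), `informative` (logical) and `gains` (named vector over
#'   all unanswered characters).
#' @export
next_best_character <- function(matrix, candidates, answered = character(0)) {
  stopifnot(length(candidates) >= 2L)
  missing <- setdiff(candidates, names(matrix$rows))
  if (length(missing))
    stop("unknown candidate row(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  open_chars <- setdiff(names(matrix$characters), answered)
  n <- length(candidates)
  gains <- stats::setNames(numeric(length(open_chars)), open_chars)
  for (ch in open_chars) {
    classes <- answer_classes(matrix, candidates, ch)
    sizes <- vapply(classes, length, numeric(1))
    sizes <- sizes[sizes > 0]
    if (length(sizes) == 0L) { gains[[ch]] <- 0; next }
    p <- sizes / sum(sizes)
    gains[[ch]] <- log2(n) - sum(p * log2(sizes))
  }
  gains <- round(gains, 12)  # guard the gain >= 0 invariant against fp noise
  if (!any(gains > 0))
    return(list(character = NA_character_, gain = 0, informative = FALSE,
                gains = gains))
  best <- sort(names(gains)[gains == max(gains)], method = "radix")[1]
  list(character = best, gain = unname(gains[[best]]), informative = TRUE,
       gains = gains)
}

#' Greedy questioning until identification
#'
#' Repeatedly asks [next_best_character()] and answers from a ground-truth
#' row until a single candidate remains or no character is informative.
#' Used to exercise the polyclave on generated keys.
#'
#' @param matrix a `dk_matrix`.
#' @param truth named list: the true values of the specimen.
#' @param max_questions safety cap.
#' @return list with `taxon` (final candidate set) and `asked` (character
#'   ids in order).
#' @export
greedy_identify <- function(matrix, truth, max_questions = 50L) {
  candidates <- names(matrix$rows)
  asked <- character(0)
  obs <- list()
  while (length(candidates) > 1L && length(asked) < max_questions) {
    nb <- next_best_character(matrix, candidates, asked)
    if (!nb$informative) break
    ch <- nb$character
    asked <- c(asked, ch)
    obs[[ch]] <- truth[[ch]]
    keep <- vapply(candidates, function(r) {
      con <- matrix$rows[[r]][[ch]]
      is.null(con) || is.na(obs[[ch]]) ||
        constraint_allows(con, obs[[ch]], matrix$characters)
    }, logical(1))
    candidates <- candidates[keep]
  }
  list(taxon = candidates, asked = asked)
}
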