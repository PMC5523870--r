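# Inverting a key into a taxon x character constraint matrix by propagating
# lead predicates along root-to-terminal paths.
#
# A constraint is, per character, either an allowed state set (binary /
# categorical / ordinal) or a canonical union of intervals (quantitative).
# Disjunctive clauses that span several characters (e.g. "attached to both
# surfaces and/or hairy trichomes") cannot be reduced to one per-character
# constraint; they are kept verbatim on the occurrence and honoured by the
# traversal sampler and the polyclave matcher.

new_constraint <- function(char_id, kind, allowed = NULL, intervals = NULL,
                           provenance = list(), polymorphic = FALSE) {
  structure(list(char_id = char_id, kind = kind, allowed = allowed,
                 intervals = intervals, provenance = provenance,
                 polymorphic = polymorphic),
            class = "dk_constraint")
}

constraint_is_empty <- function(con) {
  if (is.null(con)) return(FALSE)       # unconstrained
  if (con$kind == "set") length(con$allowed) == 0L
  else nrow(con$intervals) == 0L
}

# full (vacuous) constraint for a character
constraint_full <- function(ch) {
  if (ch$kind == "quantitative")
    new_constraint(ch$char_id, "interval", intervals = iv_full())
  else
    new_constraint(ch$char_id, "set", allowed = character_states(ch))
}

pred_constraint <- function(pred, ontology) {
  ch <- ontology[[pred$char_id]]
  if (ch$kind == "quantitative")
    new_constraint(pred$char_id, "interval",
                   intervals = iv_canonical(pred_to_interval(pred$op, pred$value)))
  else
    new_constraint(pred$char_id, "set", allowed = pred_states(pred, ontology))
}

constraint_intersect <- function(a, b, ontology) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  stopifnot(a$char_id == b$char_id, a$kind == b$kind)
  out <- a
  if (a$kind == "set") {
    states <- character_states(ontology[[a$char_id]])
    out$allowed <- states[states %in% a$allowed & states %in% b$allowed]
  } else out$intervals <- iv_intersect(a$intervals, b$intervals)
  out$provenance <- c(a$provenance, b$provenance)
  out
}

constraint_union <- function(a, b, ontology) {
  if (is.null(a) || is.null(b)) return(NULL)  # union with "anything"
  stopifnot(a$char_id == b$char_id, a$kind == b$kind)
  out <- a
  if (a$kind == "set") {
    states <- character_states(ontology[[a$char_id]])
    out$allowed <- states[states %in% union(a$allowed, b$allowed)]
  } else out$intervals <- iv_union(a$intervals, b$intervals)
  out$provenance <- c(a$provenance, b$provenance)
  out
}

constraint_disjoint <- function(a, b, ontology) {
  constraint_is_empty(constraint_intersect(a, b, ontology))
}

# does an observed value satisfy the constraint?
constraint_allows <- function(con, value, ontology) {
  if (is.null(con)) return(TRUE)
  if (con$kind == "set") as.character(value) %in% con$allowed
  else iv_contains(con$intervals, as.numeric(value))
}

# split clauses of one lead into per-character constraints and residual
# multi-character disjunctions
clauses_to_constraints <- function(clauses, ontology, provenance = NULL) {
  per_char <- list()
  disjunctions <- list()
  for (cl in clauses) {
    chars <- unique(vapply(cl, `[[`, character(1), "char_id"))
    if (length(chars) == 1L) {
      con <- NULL
      for (p in cl) {
        pc <- pred_constraint(p, ontology)
        con <- if (is.null(con)) pc else constraint_union(con, pc, ontology)
      }
      if (!is.null(provenance)) con$provenance <- list(provenance)
      per_char[[chars]] <- if (is.null(per_char[[chars]])) con
        else constraint_intersect(per_char[[chars]], con, ontology)
    } else {
      disjunctions[[length(disjunctions) + 1L]] <-
        structure(cl, provenance = provenance)
    }
  }
  list(per_char = per_char, disjunctions = disjunctions)
}

#' Invert a key into a taxon-by-character constraint matrix
#'
#' Walks every root-to-terminal path and intersects, per character, all
#' predicates encountered on the path (occurrence level).  At taxon level
#' the occurrence constraints of each taxon are united per character; the
#' polymorphic flag is set when the constrained occurrences are pairwise
#' disjoint (the taxon keys out on opposite sides of some couplet).  A
#' character never mentioned on a taxon's paths stays unconstrained rather
#' than being defaulted.  Contradictory paths (empty intersection) are
#' reported in `$contradictions`, never silently dropped.
#'
#' @param key a valid `dichokey_key`.
#' @param level `"occurrence"` or `"taxon"`.  Taxon rows are species plus
#'   non-autonym subspecies; elevation/population forms are merged into
#'   their species.
#' @return an object of class `dk_matrix`: list with `level`, `characters`,
#'   `rows` (named list: per row a named list of `dk_constraint`),
#'   `disjunctions` (per row), `occurrence_rows` (occurrence-level
#'   sub-matrix, retained at taxon level), and `contradictions`.
#' @examples
#' key <- load_fixture("syagrus_key")
#' m <- induce_matrix(key, "taxon")
#' constraint_of(m, "S. macrocarpa", "lamina_thickness")
#' @export
induce_matrix <- function(key, level = c("occurrence", "taxon")) {
  level <- match.arg(level)
  ontology <- key$characters
  terms <- key_terminal_leads(key)
  occ_rows <- list(); occ_disj <- list(); contradictions <- list()
  for (ld in terms) {
    occ <- ld$target$occurrence
    lbl <- occ_label(occ)
    leads <- path_leads(key, occ)
    per_char <- list(); disjs <- list()
    for (pl in leads) {
      cc <- clauses_to_constraints(pl$clauses, ontology,
                                   provenance = c(pl$couplet, pl$slot))
      for (ch in names(cc$per_char)) {
        per_char[[ch]] <- if (is.null(per_char[[ch]])) cc$per_char[[ch]]
          else constraint_intersect(per_char[[ch]], cc$per_char[[ch]], ontology)
      }
      disjs <- c(disjs, cc$disjunctions)
    }
    for (ch in names(per_char))
      if (constraint_is_empty(per_char[[ch]]))
        contradictions[[length(contradictions) + 1L]] <-
          data.frame(row = lbl, char_id = ch)
    occ_rows[[lbl]] <- per_char
    occ_disj[[lbl]] <- disjs
  }
  occs <- key_occurrences(key)

  if (level == "occurrence") {
    rows <- occ_rows; disj <- occ_disj
  } else {
    groups <- split(vapply(occs, occ_label, character(1)),
                    vapply(occs, function(o) taxon_of(o$name), character(1)))
    rows <- list(); disj <- list()
    for (tx in names(groups)) {
      members <- groups[[tx]]
      per_char <- list()
      all_chars <- unique(unlist(lapply(members, function(m) names(occ_rows[[m]]))))
      for (ch in all_chars) {
        cons <- lapply(members, function(m) occ_rows[[m]][[ch]])
        if (any(vapply(cons, is.null, logical(1)))) next  # union with unconstrained
        con <- cons[[1]]
        for (k in seq_along(cons)[-1])
          con <- constraint_union(con, cons[[k]], key$characters)
        if (length(cons) > 1L) {
          pairs_disjoint <- TRUE
          for (i in seq_along(cons)) for (j in seq_along(cons)) {
            if (i < j && !constraint_disjoint(cons[[i]], cons[[j]], ontology))
              pairs_disjoint <- FALSE
          }
          con$polymorphic <- pairs_disjoint
        }
        per_char[[ch]] <- con
      }
      rows[[tx]] <- per_char
      disj[[tx]] <- unlist(lapply(members, function(m) occ_disj[[m]]),
                           recursive = FALSE)
    }
    ord <- sort(names(rows), method = "radix")
    rows <- rows[ord]; disj <- disj[ord]
  }
  structure(list(level = level, characters = ontology, rows = rows,
                 disjunctions = disj, occurrence_rows = occ_rows,
                 occurrence_disjunctions = occ_disj,
                 contradictions = if (length(contradictions))
                   do.call(rbind, contradictions)
                 else data.frame(row = character(0), char_id = character(0))),
            class = "dk_matrix")
}

#' @export
print.dk_matrix <- function(x, ...) {
  cat(sprintf("Induced %s-level matrix: %d rows x %d characters; %d contradiction(s)\n",
              x$level, length(x$rows), length(x$characters),
              nrow(x$contradictions)))
  invisible(x)
}

#' Look up one constraint of an induced matrix
#'
#' @param matrix a `dk_matrix`.
#' @param taxon a row name (taxon or occurrence label, depending on the
#'   matrix level).
#' @param character a `char_id`.
#' @return the `dk_constraint`, or the string `"unconstrained"` when the
#'   character is never mentioned on the row's paths.
#' @export
constraint_of <- function(matrix, taxon, character) {
  if (!taxon %in% names(matrix$rows))
    stop(sprintf("unknown %s '%s'", matrix$level, taxon), call. = FALSE)
  if (!character %in% names(matrix$characters))
    stop(sprintf("unknown character '%s'", character), call. = FALSE)
  con <- matrix$rows[[taxon]][[character]]
  if (is.null(con)) "unconstrained" else con
}

#' @export
format.dk_constraint <- function(x, ...) {
  body <- if (x$kind == "set") {
    paste0("{", paste(sort(x$allowed, method = "radix"), collapse = ","), "}")
  } else {
    fmt1 <- function(i) {
      r <- x$intervals[i, ]
      paste0(if (r$lo_open) "(" else "[",
             if (is.finite(r$lo)) num_str(r$lo) else "-inf", "..",
             if (is.finite(r$hi)) num_str(r$hi) else "inf",
             if (r$hi_open) ")" else "]")
    }
    paste(vapply(seq_len(nrow(x$intervals)), fmt1, character(1)),
          collapse = "U")
  }
  if (isTRUE(x$polymorphic)) paste0("poly:", body) else body
}

#' @export
print.dk_constraint <- function(x, ...) {
  cat(sprintf("<constraint %s: %s>\n", x$char_id, format(x)))
  invisible(x)
}

parse_constraint_cell <- function(cell, ch) {
  if (!nzchar(cell)) return(NULL)
  poly <- startsWith(cell, "poly:")
  if (poly) cell <- sub("^poly:", "", cell)
  if (startsWith(cell, "{")) {
    inner <- substr(cell, 2L, nchar(cell) - 1L)
    allowed <- if (nzchar(inner)) strsplit(inner, ",", fixed = TRUE)[[1]]
               else character(0)
    states <- character_states(ch)
    new_constraint(ch$char_id, "set", allowed = states[states %in% allowed],
                   polymorphic = poly)
  } else {
    rows <- lapply(strsplit(cell, "U", fixed = TRUE)[[1]], function(piece) {
      lo_open <- startsWith(piece, "(")
      hi_open <- endsWith(piece, ")")
      body <- substr(piece, 2L, nchar(piece) - 1L)
      ends <- strsplit(body, "..", fixed = TRUE)[[1]]
      lo <- if (identical(ends[1], "-inf")) -Inf else as.numeric(ends[1])
      hi <- if (identical(ends[2], "inf")) Inf else as.numeric(ends[2])
      iv(lo, hi, lo_open, hi_open)
    })
    new_constraint(ch$char_id, "interval",
                   intervals = iv_canonical(do.call(rbind, rows)),
                   polymorphic = poly)
  }
}

#' Export an induced matrix as CSV text
#'
#' One row per taxon (or occurrence), one column per character, in ontology
#' order.  State sets render as `{a,b}` (sorted), interval unions as
#' `[lo..hi]` pieces joined by `U` with `(`/`)` marking open ends and
#' `-inf`/`inf` for unbounded ends; polymorphic constraints carry a `poly:`
#' prefix; unconstrained cells are empty.  [parse_matrix_csv()] restores all
#' constraints (round trip).
#'
#' @param matrix a `dk_matrix`.
#' @param file optional path; when given the text is also written there.
#' @return the CSV text, invisibly when `file` is given.
#' @export
export_matrix <- function(matrix, file = NULL) {
  chars <- names(matrix$characters)
  rows <- names(matrix$rows)
  tab <- data.frame(taxon = rows, check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (ch in chars)
    tab[[ch]] <- vapply(rows, function(r) {
      con <- matrix$rows[[r]][[ch]]
      if (is.null(con)) "" else format(con)
    }, character(1))
  con <- textConnection("out", "w", local = TRUE)
  utils::write.csv(tab, con, row.names = FALSE, quote = TRUE)
  close(con)
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(file)) { writeLines(text, file, sep = ""); return(invisible(text)) }
  text
}

#' Deterministic observation satisfying a matrix row
#'
#' Builds an observation that satisfies every per-character constraint of
#' the row (first allowed state, or a point inside the first interval) and,
#' where the row carries multi-character disjunctions, additionally
#' satisfies each of them.  Used to check the soundness property that
#' traversing the key with any assignment satisfying an occurrence's
#' constraints reaches that occurrence.
#'
#' @param matrix a `dk_matrix`.
#' @param row a row name.
#' @return named list of values.
#' @export
sample_observation <- function(matrix, row) {
  if (!row %in% names(matrix$rows))
    stop(sprintf("unknown %s '%s'", matrix$level, row), call. = FALSE)
  per_char <- matrix$rows[[row]]
  ont <- matrix$characters
  pick <- function(con) {
    if (con$kind == "set") con$allowed[1] else iv_sample_point(con$intervals)
  }
  obs <- lapply(per_char, pick)
  for (cl in matrix$disjunctions[[row]]) {
    sat <- vapply(cl, function(p)
      isTRUE(eval_predicate(p, obs[[p$char_id]], ont)), logical(1))
    if (any(sat)) next
    for (p in cl) {
      pc <- pred_constraint(p, ont)
      comb <- if (is.null(per_char[[p$char_id]])) pc
              else constraint_intersect(pc, per_char[[p$char_id]], ont)
      if (!constraint_is_empty(comb)) { obs[[p$char_id]] <- pick(comb); break }
    }
  }
  obs
}

#' Re-read a matrix CSV written by [export_matrix()]
#'
#' @param text CSV text (or a file path to one).
#' @param ontology the character ontology the matrix was built against (a
#'   key or named list of `dk_character`).
#' @param level level label to attach (`"taxon"` by default).
#' @return a `dk_matrix` (without occurrence sub-rows or disjunctions).
#' @export
parse_matrix_csv <- function(text, ontology, level = "taxon") {
  ontology <- as_ontology(ontology)
  tab <- if (length(text) == 1L && file.exists(text))
    utils::read.csv(text, check.names = FALSE, colClasses = "character")
  else utils::read.csv(text = text, check.names = FALSE,
                       colClasses = "character")
  rows <- list()
  for (i in seq_len(nrow(tab))) {
    per_char <- list()
    for (ch in setdiff(names(tab), "taxon")) {
      con <- parse_constraint_cell(tab[[ch]][i], ontology[[ch]])
      if (!is.null(con)) per_char[[ch]] <- con
    }
    rows[[tab$taxon[i]]] <- per_char
  }
  structure(list(level = level, characters = ontology, rows = rows,
                 disjunctions = stats::setNames(vector("list", length(rows)),
                                                names(rows)),
                 occurrence_rows = NULL,
                 contradictions = data.frame(row = character(0),
                                             char_id = character(0))),
            class = "dk_matrix")
}
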