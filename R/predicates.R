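# Predicate mini-DSL and the interval/state-set algebra behind constraints.
#
# Grammar (one lead's `predicates` field):
#   expression := clause (";" clause)*          conjunction
#   clause     := atom ("|" atom)*              disjunction
#   atom       := char_id op value
#   op         := "=" | "!=" | "<" | "<=" | ">" | ">=" | "in"
#   value      := state | "{" state ("," state)* "}" | number
#               | number ".." number | number ".." | ".." number
# Intervals written "a..b" are closed at finite ends; "a.." means [a, Inf),
# "..b" means (-Inf, b].  Open bounds arise only from strict comparisons.

DK_OPS <- c("eq", "ne", "lt", "le", "gt", "ge", "in_set", "in_interval")

new_predicate <- function(char_id, op, value) {
  stopifnot(op %in% DK_OPS)
  structure(list(char_id = char_id, op = op, value = value),
            class = "dk_predicate")
}

# ---- interval unions ------------------------------------------------------
# An interval union is a data.frame(lo, hi, lo_open, hi_open), canonicalised:
# rows sorted, pairwise disjoint, none empty.

iv <- function(lo, hi, lo_open = FALSE, hi_open = FALSE) {
  data.frame(lo = lo, hi = hi, lo_open = lo_open, hi_open = hi_open)
}

iv_is_empty_row <- function(r) {
  r$lo > r$hi || (r$lo == r$hi && (r$lo_open || r$hi_open))
}

iv_full <- function() iv(-Inf, Inf, TRUE, TRUE)

iv_canonical <- function(x) {
  if (is.null(x) || nrow(x) == 0L) return(iv(numeric(0), numeric(0), logical(0), logical(0)))
  keep <- !vapply(seq_len(nrow(x)), function(i) iv_is_empty_row(x[i, ]), logical(1))
  x <- x[keep, , drop = FALSE]
  if (nrow(x) == 0L) return(x)
  x <- x[order(x$lo, x$lo_open), , drop = FALSE]
  out <- x[1, , drop = FALSE]
  for (i in seq_len(nrow(x))[-1]) {
    cur <- out[nrow(out), ]
    nxt <- x[i, ]
    # mergeable if intervals overlap or touch with at least one closed end
    touches <- nxt$lo < cur$hi ||
      (nxt$lo == cur$hi && !(nxt$lo_open && cur$hi_open))
    if (touches) {
      if (nxt$hi > cur$hi || (nxt$hi == cur$hi && !nxt$hi_open)) {
        out[nrow(out), "hi"] <- nxt$hi
        out[nrow(out), "hi_open"] <- nxt$hi_open
      }
    } else {
      out <- rbind(out, nxt)
    }
  }
  rownames(out) <- NULL
  out
}

iv_intersect <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(iv_canonical(a[0, ]))
  rows <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    lo <- max(a$lo[i], b$lo[j])
    lo_open <- if (a$lo[i] == b$lo[j]) a$lo_open[i] || b$lo_open[j]
               else if (a$lo[i] > b$lo[j]) a$lo_open[i] else b$lo_open[j]
    hi <- min(a$hi[i], b$hi[j])
    hi_open <- if (a$hi[i] == b$hi[j]) a$hi_open[i] || b$hi_open[j]
               else if (a$hi[i] < b$hi[j]) a$hi_open[i] else b$hi_open[j]
    rows[[length(rows) + 1L]] <- iv(lo, hi, lo_open, hi_open)
  }
  iv_canonical(do.call(rbind, rows))
}

iv_union <- function(a, b) iv_canonical(rbind(a, b))

iv_contains <- function(x, value) {
  if (nrow(x) == 0L) return(FALSE)
  any(vapply(seq_len(nrow(x)), function(i) {
    lo_ok <- value > x$lo[i] || (value == x$lo[i] && !x$lo_open[i])
    hi_ok <- value < x$hi[i] || (value == x$hi[i] && !x$hi_open[i])
    lo_ok && hi_ok
  }, logical(1)))
}

# a representative point inside each interval of a union (used by samplers)
iv_sample_point <- function(x) {
  stopifnot(nrow(x) > 0L)
  r <- x[1, ]
  if (is.finite(r$lo) && is.finite(r$hi)) {
    if (r$lo == r$hi) r$lo else (r$lo + r$hi) / 2
  } else if (is.finite(r$lo)) {
    if (r$lo_open) r$lo + 1 else r$lo
  } else if (is.finite(r$hi)) {
    if (r$hi_open) r$hi - 1 else r$hi
  } else 0
}

pred_to_interval <- function(op, value) {
  switch(op,
    lt = iv(-Inf, value, TRUE, TRUE),
    le = iv(-Inf, value, TRUE, FALSE),
    gt = iv(value, Inf, TRUE, TRUE),
    ge = iv(value, Inf, FALSE, TRUE),
    in_interval = iv(value[1], value[2],
                     lo_open = !is.finite(value[1]),
                     hi_open = !is.finite(value[2])),
    stop("not an interval-valued operator: ", op))
}

# ---- parsing --------------------------------------------------------------

dk_syntax_error <- function(text, offset, what) {
  stop(sprintf("predicate syntax error at offset %d in \"%s\": %s",
               offset, text, what), call. = FALSE)
}

num_str <- function(x) {
  if (!is.finite(x)) return("")
  format(x, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
}

parse_atom <- function(atom, text, base_offset, ontology) {
  s <- atom
  # leading whitespace
  ws <- regmatches(s, regexpr("^\\s*", s))
  off <- base_offset + nchar(ws)
  s <- sub("^\\s*", "", s)
  m <- regexpr("^[A-Za-z_][A-Za-z0-9_.]*", s)
  if (m == -1L) dk_syntax_error(text, off, "expected character id")
  char_id <- regmatches(s, m)
  s <- substring(s, attr(m, "match.length") + 1L)
  off <- off + attr(m, "match.length")
  ws <- regmatches(s, regexpr("^\\s*", s))
  off <- off + nchar(ws); s <- sub("^\\s*", "", s)
  op_tok <- NULL
  for (tok in c("!=", "<=", ">=", "<", ">", "=", "in ")) {
    if (startsWith(s, tok)) { op_tok <- tok; break }
  }
  if (startsWith(s, "in{")) op_tok <- "in "  # allow "in{...}" without space
  if (is.null(op_tok)) dk_syntax_error(text, off, "expected operator")
  op_len <- if (op_tok == "in ") 2L else nchar(op_tok)
  s <- substring(s, op_len + 1L)
  off <- off + op_len
  ws <- regmatches(s, regexpr("^\\s*", s))
  off <- off + nchar(ws); s <- sub("^\\s*", "", s)
  val_txt <- sub("\\s*$", "", s)
  if (!nzchar(val_txt)) dk_syntax_error(text, off, "expected value")

  ch <- ontology[[char_id]]
  if (is.null(ch))
    stop(sprintf("unknown character '%s' in predicate \"%s\"", char_id, text),
         call. = FALSE)
  kind <- ch$kind
  states <- character_states(ch)

  check_state <- function(st) {
    if (!st %in% states)
      stop(sprintf("unknown state '%s' for character '%s' (have: %s)",
                   st, char_id, paste(states, collapse = ", ")), call. = FALSE)
    st
  }
  parse_num <- function(txt, at) {
    v <- suppressWarnings(as.numeric(txt))
    if (is.na(v)) dk_syntax_error(text, at, sprintf("invalid number \"%s\"", txt))
    v
  }

  if (op_tok %in% c("=", "!=")) {
    op <- if (op_tok == "=") "eq" else "ne"
    if (kind == "quantitative") {
      return(new_predicate(char_id, op, parse_num(val_txt, off)))
    }
    return(new_predicate(char_id, op, check_state(val_txt)))
  }
  if (op_tok %in% c("<", "<=", ">", ">=")) {
    op <- c("<" = "lt", "<=" = "le", ">" = "gt", ">=" = "ge")[[op_tok]]
    if (kind == "quantitative")
      return(new_predicate(char_id, op, parse_num(val_txt, off)))
    if (kind == "ordinal")
      return(new_predicate(char_id, op, check_state(val_txt)))
    stop(sprintf("comparison '%s' not allowed on %s character '%s'",
                 op_tok, kind, char_id), call. = FALSE)
  }
  # "in": set or interval
  if (startsWith(val_txt, "{")) {
    if (!endsWith(val_txt, "}"))
      dk_syntax_error(text, off + nchar(val_txt) - 1L, "unterminated set")
    if (kind == "quantitative")
      stop(sprintf("state set not allowed on quantitative character '%s'",
                   char_id), call. = FALSE)
    inner <- substr(val_txt, 2L, nchar(val_txt) - 1L)
    sts <- trimws(strsplit(inner, ",", fixed = TRUE)[[1]])
    sts <- sts[nzchar(sts)]
    if (length(sts) == 0L) dk_syntax_error(text, off, "empty set")
    vapply(sts, check_state, character(1))
    return(new_predicate(char_id, "in_set", unname(sts)))
  }
  if (grepl("..", val_txt, fixed = TRUE)) {
    if (kind != "quantitative")
      stop(sprintf("interval not allowed on %s character '%s'", kind, char_id),
           call. = FALSE)
    parts <- strsplit(val_txt, "..", fixed = TRUE)[[1]]
    if (length(parts) > 2L) dk_syntax_error(text, off, "malformed interval")
    lo_txt <- if (length(parts) >= 1L) parts[1] else ""
    hi_txt <- if (length(parts) == 2L) parts[2] else ""
    lo <- if (nzchar(trimws(lo_txt))) parse_num(trimws(lo_txt), off) else -Inf
    hi <- if (nzchar(trimws(hi_txt))) parse_num(trimws(hi_txt), off) else Inf
    if (lo > hi)
      stop(sprintf("interval lower bound exceeds upper in \"%s\"", val_txt),
           call. = FALSE)
    return(new_predicate(char_id, "in_interval", c(lo, hi)))
  }
  if (kind == "quantitative")
    dk_syntax_error(text, off, sprintf("expected number or interval, got \"%s\"", val_txt))
  # bare state after "in" treated as singleton set
  new_predicate(char_id, "in_set", check_state(val_txt))
}

#' Parse a predicate expression in the lead mini-DSL
#'
#' An expression is a conjunction of clauses separated by `";"`; each clause
#' is a disjunction of atoms separated by `"|"`.  Atoms compare one character
#' against a state (`=`, `!=`), a state set (`in {a,b}`), a number
#' (`<`, `<=`, `>`, `>=`) or an interval (`in a..b`, `in a..`, `in ..b`).
#' Interval bounds written with `".."` are closed at finite ends; open bounds
#' come only from strict comparisons.  Strict/ordered comparisons are allowed
#' on quantitative and ordinal characters; set operators on binary,
#' categorical and ordinal characters.
#'
#' @param text expression source text.
#' @param ontology a character ontology (named list as in [parse_key()], or a
#'   `dichokey_key` whose `$characters` is used).
#' @return an object of class `dk_clauses`: a list of clauses, each clause a
#'   list of predicates `list(char_id, op, value)`, with the source text kept
#'   in attribute `"source"`.
#' @examples
#' key <- load_fixture("syagrus_key")
#' parse_predicates("lamina_thickness<0.25", key)
#' parse_predicates("abaxial_minor_vein_count in 9..", key)
#' @export
parse_predicates <- function(text, ontology) {
  ontology <- as_ontology(ontology)
  stopifnot(is.character(text), length(text) == 1L)
  clauses <- list()
  pos <- 0L
  for (clause_txt in strsplit(text, ";", fixed = TRUE)[[1]]) {
    disjuncts <- list()
    cpos <- pos
    for (atom_txt in strsplit(clause_txt, "|", fixed = TRUE)[[1]]) {
      disjuncts[[length(disjuncts) + 1L]] <-
        parse_atom(atom_txt, text, cpos, ontology)
      cpos <- cpos + nchar(atom_txt) + 1L
    }
    clauses[[length(clauses) + 1L]] <- disjuncts
    pos <- pos + nchar(clause_txt) + 1L
  }
  structure(clauses, class = "dk_clauses", source = text)
}

#' Render parsed predicates back to the mini-DSL
#'
#' Inverse of [parse_predicates()]: `parse_predicates(render_predicates(p))`
#' is structurally identical to `p` and rendering is canonical (single
#' spelling per predicate), which gives byte-stable key files.
#'
#' @param clauses a `dk_clauses` object (or bare list of clauses).
#' @return a single string in the mini-DSL.
#' @export
render_predicates <- function(clauses) {
  render_atom <- function(p) {
    v <- p$value
    switch(p$op,
      eq = paste0(p$char_id, "=", v),
      ne = paste0(p$char_id, "!=", v),
      lt = paste0(p$char_id, "<", if (is.numeric(v)) num_str(v) else v),
      le = paste0(p$char_id, "<=", if (is.numeric(v)) num_str(v) else v),
      gt = paste0(p$char_id, ">", if (is.numeric(v)) num_str(v) else v),
      ge = paste0(p$char_id, ">=", if (is.numeric(v)) num_str(v) else v),
      in_set = if (length(v) == 1L) paste0(p$char_id, "=", v)
               else paste0(p$char_id, " in {", paste(v, collapse = ","), "}"),
      in_interval = paste0(p$char_id, " in ", num_str(v[1]), "..", num_str(v[2])),
      stop("bad op"))
  }
  paste(vapply(clauses, function(cl)
    paste(vapply(cl, render_atom, character(1)), collapse = "|"),
    character(1)), collapse = ";")
}

# ---- evaluation -----------------------------------------------------------

ordinal_rank <- function(states, value) match(value, states)

# evaluate one predicate against an observed value; NA value = unknown -> NA
eval_predicate <- function(pred, value, ontology) {
  if (is.null(value) || (length(value) == 1L && is.na(value))) return(NA)
  ch <- ontology[[pred$char_id]]
  kind <- ch$kind
  if (kind == "quantitative") {
    v <- as.numeric(value)
    switch(pred$op,
      eq = v == pred$value, ne = v != pred$value,
      lt = v < pred$value, le = v <= pred$value,
      gt = v > pred$value, ge = v >= pred$value,
      in_interval = iv_contains(pred_to_interval("in_interval", pred$value), v),
      in_set = stop("in_set on quantitative character"))
  } else {
    states <- character_states(ch)
    switch(pred$op,
      eq = value == pred$value,
      ne = value != pred$value,
      in_set = value %in% pred$value,
      lt = ordinal_rank(states, value) < ordinal_rank(states, pred$value),
      le = ordinal_rank(states, value) <= ordinal_rank(states, pred$value),
      gt = ordinal_rank(states, value) > ordinal_rank(states, pred$value),
      ge = ordinal_rank(states, value) >= ordinal_rank(states, pred$value))
  }
}

# clause (disjunction): TRUE if any disjunct TRUE; FALSE if all FALSE; else NA
eval_clause <- function(clause, observation, ontology) {
  vals <- vapply(clause, function(p) {
    v <- observation[[p$char_id]]
    r <- eval_predicate(p, v, ontology)
    if (is.na(r)) NA else r
  }, logical(1))
  if (any(vals %in% TRUE)) TRUE
  else if (all(vals %in% FALSE)) FALSE
  else NA
}

# lead (conjunction of clauses): TRUE / FALSE / NA (undetermined)
eval_clauses <- function(clauses, observation, ontology) {
  vals <- vapply(clauses, eval_clause, logical(1),
                 observation = observation, ontology = ontology)
  if (any(vals %in% FALSE)) FALSE
  else if (all(vals %in% TRUE)) TRUE
  else NA
}

# predicate -> constraint contribution on its own character
pred_states <- function(pred, ontology) {
  ch <- ontology[[pred$char_id]]
  states <- character_states(ch)
  switch(pred$op,
    eq = pred$value,
    ne = setdiff(states, pred$value),
    in_set = states[states %in% pred$value],
    lt = states[seq_len(max(0L, ordinal_rank(states, pred$value) - 1L))],
    le = states[seq_len(ordinal_rank(states, pred$value))],
    gt = states[seq(ordinal_rank(states, pred$value) + 1L, length.out =
                      length(states) - ordinal_rank(states, pred$value))],
    ge = states[seq(ordinal_rank(states, pred$value), length(states))],
    stop("not a state predicate"))
}
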