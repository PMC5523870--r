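# Executing a key against observations; paths, branches and key metrics.

#' Parse / format a branch label
#'
#' A branch label names one lead: `"53"` is lead a of couplet 53, `"57'"`
#' (ASCII apostrophe or Unicode prime) lead b of couplet 57.  The virtual
#' label `"ROOT"` denotes the whole key.
#'
#' @param label branch label string.
#' @return a list `list(couplet, slot)` or the string `"ROOT"`.
#' @export
parse_branch_label <- function(label) {
  if (identical(toupper(label), "ROOT")) return("ROOT")
  label <- gsub("′", "'", label)
  m <- regmatches(label, regexec("^(\\d+)('?)$", label))[[1]]
  if (length(m) == 0L)
    stop(sprintf("malformed branch label \"%s\"", label), call. = FALSE)
  list(couplet = as.integer(m[2]), slot = if (nzchar(m[3])) "b" else "a")
}

format_branch_label <- function(couplet, slot) {
  paste0(couplet, if (slot == "b") "'" else "")
}

# parent lead of each couplet: named list couplet_id -> c(parent, slot)
key_parents <- function(key) {
  parents <- list()
  for (ld in key_leads(key))
    if (ld$target$kind == "couplet")
      parents[[as.character(ld$target$couplet)]] <- list(couplet = ld$couplet,
                                                         slot = ld$slot)
  parents
}

#' Root-to-terminal path of an occurrence
#'
#' @param key a valid `dichokey_key`.
#' @param occurrence a `dk_occurrence` or an occurrence label such as
#'   `"S. cardenasii#1"` (the `#1` may be omitted when unambiguous).
#' @return integer vector of couplet ids from the root to the terminal lead.
#' @examples
#' key <- load_fixture("syagrus_key")
#' path_to(key, "S. cardenasii#1")   # 1 37 46 51 53 57 60 70 71
#' @export
path_to <- function(key, occurrence) {
  ld <- find_terminal_lead(key, occurrence)
  ids <- integer(0)
  cur <- list(couplet = ld$couplet, slot = ld$slot)
  parents <- key_parents(key)
  while (!is.null(cur)) {
    ids <- c(cur$couplet, ids)
    cur <- parents[[as.character(cur$couplet)]]
  }
  ids
}

find_terminal_lead <- function(key, occurrence) {
  want <- if (inherits(occurrence, "dk_occurrence")) occ_label(occurrence)
          else as.character(occurrence)
  terms <- key_terminal_leads(key)
  labels <- vapply(terms, function(l) occ_label(l$target$occurrence),
                   character(1))
  hit <- which(labels == want)
  if (length(hit) == 0L && !grepl("#\\d+$", want)) {
    hit <- which(labels == paste0(want, "#1"))
    if (length(hit) == 0L)
      hit <- which(sub("#\\d+$", "", labels) == want)
  }
  if (length(hit) == 0L)
    stop(sprintf("unknown occurrence \"%s\"", want), call. = FALSE)
  if (length(hit) > 1L)
    stop(sprintf("occurrence \"%s\" is ambiguous (%s)", want,
                 paste(labels[hit], collapse = ", ")), call. = FALSE)
  terms[[hit]]
}

# sequence of leads (not couplets) from root down to an occurrence's terminal
path_leads <- function(key, occurrence) {
  ids <- path_to(key, occurrence)
  out <- vector("list", length(ids))
  nxt <- ids[-1]
  for (i in seq_along(ids)) {
    cp <- key$couplets[[as.character(ids[i])]]
    if (i < length(ids)) {
      slot <- if (cp$leads$a$target$kind == "couplet" &&
                  cp$leads$a$target$couplet == nxt[i]) "a" else "b"
    } else {
      want <- if (inherits(occurrence, "dk_occurrence")) occ_label(occurrence)
              else as.character(occurrence)
      slot <- if (cp$leads$a$target$kind == "taxon" &&
                  startsWith(want, sub("#\\d+$", "",
                                       occ_label(cp$leads$a$target$occurrence))) &&
                  occ_matches(cp$leads$a$target$occurrence, want)) "a" else "b"
    }
    out[[i]] <- cp$leads[[slot]]
  }
  out
}

occ_matches <- function(occ, want) {
  lbl <- occ_label(occ)
  identical(lbl, want) || identical(sub("#\\d+$", "", lbl), want) ||
    identical(lbl, paste0(want, "#1"))
}

#' Traverse a key with an observation
#'
#' In `strict` mode the key is answered couplet by couplet from the root: a
#' lead matches when every clause of its predicate expression evaluates
#' true, fails when any clause evaluates false, and is undetermined
#' otherwise (unanswered character).  Exactly one matching lead is followed;
#' both leads matching stops with status `"contradiction"`; no matching lead
#' stops with status `"ambiguous"` and the couplet recorded in
#' `unresolved`, which supports interactive prompting.  In `explore` mode
#' every non-failing lead is descended and the union of reachable terminals
#' is returned, the field-use case of a partial specimen.
#'
#' @param key a valid `dichokey_key`.
#' @param observation named list/vector of observed values (`NA` = unknown);
#'   see [read_observations()].
#' @param mode `"strict"` or `"explore"`.
#' @return a list of class `dk_traversal`: `status` (`identified`,
#'   `ambiguous` or `contradiction`), `path` (data.frame couplet/slot, strict
#'   mode), `outcomes` (occurrence labels), `unresolved` (couplet ids).
#' @examples
#' key <- load_fixture("syagrus_key")
#' obs <- list(adaxial_fb_extent = "over_one_third",
#'             mesophyll_minor_veins = "few",
#'             marginal_vein_exaggerated = "small",
#'             adaxial_minor_veins = "absent",
#'             lamina_thickness = 0.2)
#' traverse_key(key, obs)$outcomes   # "S. macrocarpa#1"
#' @export
traverse_key <- function(key, observation, mode = c("strict", "explore")) {
  mode <- match.arg(mode)
  observation <- check_observation(observation, key$characters)
  ontology <- key$characters
  if (mode == "strict") {
    path <- list(); id <- key$root
    repeat {
      cp <- key$couplets[[as.character(id)]]
      ra <- eval_clauses(cp$leads$a$clauses, observation, ontology)
      rb <- eval_clauses(cp$leads$b$clauses, observation, ontology)
      if (isTRUE(ra) && isTRUE(rb))
        return(traversal_result("contradiction", path, character(0), id))
      slot <- if (isTRUE(ra)) "a" else if (isTRUE(rb)) "b" else NA
      if (is.na(slot))
        return(traversal_result("ambiguous", path, character(0), id))
      path[[length(path) + 1L]] <- data.frame(couplet = id, slot = slot)
      tg <- cp$leads[[slot]]$target
      if (tg$kind == "taxon")
        return(traversal_result("identified", path,
                                occ_label(tg$occurrence), integer(0)))
      id <- tg$couplet
    }
  }
  # explore: descend all non-failing leads
  outcomes <- character(0); unresolved <- integer(0)
  stack <- key$root
  while (length(stack)) {
    id <- stack[[1]]; stack <- stack[-1]
    cp <- key$couplets[[as.character(id)]]
    any_open <- FALSE
    for (slot in c("a", "b")) {
      r <- eval_clauses(cp$leads[[slot]]$clauses, observation, ontology)
      if (!isFALSE(r)) {
        any_open <- TRUE
        if (is.na(r)) unresolved <- union(unresolved, id)
        tg <- cp$leads[[slot]]$target
        if (tg$kind == "taxon") outcomes <- c(outcomes, occ_label(tg$occurrence))
        else stack <- c(stack, tg$couplet)
      }
    }
    if (!any_open) unresolved <- union(unresolved, id)
  }
  status <- if (length(outcomes) == 1L) "identified"
            else if (length(outcomes) == 0L) "contradiction" else "ambiguous"
  traversal_result(status, list(), sort(outcomes, method = "radix"),
                   unresolved)
}

traversal_result <- function(status, path, outcomes, unresolved) {
  structure(list(status = status,
                 path = if (length(path)) do.call(rbind, path)
                        else data.frame(couplet = integer(0),
                                        slot = character(0)),
                 outcomes = outcomes, unresolved = unresolved),
            class = "dk_traversal")
}

#' @export
print.dk_traversal <- function(x, ...) {
  cat(sprintf("Traversal: %s; %d outcome(s)\n", x$status, length(x$outcomes)))
  if (nrow(x$path))
    cat("  path:", paste(paste0(x$path$couplet,
                                ifelse(x$path$slot == "b", "'", "")),
                         collapse = " -> "), "\n")
  if (length(x$outcomes) && length(x$outcomes) <= 10L)
    cat("  outcomes:", paste(x$outcomes, collapse = ", "), "\n")
  if (length(x$unresolved))
    cat("  unresolved couplets:", paste(x$unresolved, collapse = ", "), "\n")
  invisible(x)
}

check_observation <- function(observation, ontology) {
  if (is.null(observation)) return(list())
  observation <- as.list(observation)
  for (ch in names(observation)) {
    def <- ontology[[ch]]
    if (is.null(def))
      stop(sprintf("observation references unknown character '%s'", ch),
           call. = FALSE)
    v <- observation[[ch]]
    if (length(v) != 1L)
      stop(sprintf("observation value for '%s' must be a scalar", ch),
           call. = FALSE)
    if (is.na(v)) next
    if (def$kind == "quantitative") {
      vn <- suppressWarnings(as.numeric(v))
      if (is.na(vn))
        stop(sprintf("non-numeric value \"%s\" for quantitative character '%s'",
                     v, ch), call. = FALSE)
      observation[[ch]] <- vn
    } else {
      if (!as.character(v) %in% character_states(def))
        stop(sprintf("value \"%s\" is not a state of character '%s'", v, ch),
             call. = FALSE)
      observation[[ch]] <- as.character(v)
    }
  }
  observation
}

# occurrence labels in the subtree below a lead (or below a couplet)
subtree_occurrences <- function(key, couplet, slot = NULL) {
  out <- character(0)
  collect <- function(ld) {
    if (ld$target$kind == "taxon")
      out <<- c(out, occ_label(ld$target$occurrence))
    else {
      cp <- key$couplets[[as.character(ld$target$couplet)]]
      collect(cp$leads$a); collect(cp$leads$b)
    }
  }
  cp <- key$couplets[[as.character(couplet)]]
  if (is.null(cp)) stop(sprintf("unknown couplet %s", couplet), call. = FALSE)
  if (is.null(slot)) { collect(cp$leads$a); collect(cp$leads$b) }
  else collect(cp$leads[[slot]])
  out
}

#' Taxa below a key branch
#'
#' Returns every taxon with at least one occurrence in the subtree below the
#' given lead; `"ROOT"` returns all taxa.
#'
#' @param key a valid `dichokey_key`.
#' @param branch_label a branch label (see [parse_branch_label()]).
#' @param level `"occurrences"` (labels) or `"species"` (collapsed names).
#' @return sorted character vector.
#' @examples
#' key <- load_fixture("syagrus_key")
#' branch_membership(key, "53", "species")
#' @export
branch_membership <- function(key, branch_label,
                              level = c("occurrences", "species")) {
  level <- match.arg(level)
  br <- parse_branch_label(branch_label)
  occs <- if (identical(br, "ROOT")) key_taxa(key, "occurrences")
          else {
            if (!as.character(br$couplet) %in% names(key$couplets))
              stop(sprintf("unknown branch label \"%s\"", branch_label),
                   call. = FALSE)
            subtree_occurrences(key, br$couplet, br$slot)
          }
  if (level == "occurrences") return(sort(occs, method = "radix"))
  sort(unique(species_of(sub("#\\d+$", "", sub(" \\([^)]*\\)", "", occs)))),
       method = "radix")
}

#' Structural metrics of a key
#'
#' Depth of a terminal is the number of couplets answered on its path.
#' Under a uniform prior over terminal occurrences the expected number of
#' couplets to an identification equals the mean terminal depth.
#'
#' @param key a valid `dichokey_key`.
#' @return list with `min_depth`, `max_depth`, `mean_depth`,
#'   `expected_couplets`, `depths` (named by occurrence label) and
#'   `subtree_sizes` (occurrences below each couplet).
#' @export
key_metrics <- function(key) {
  occs <- key_taxa(key, "occurrences")
  depths <- vapply(occs, function(o) length(path_to(key, o)), numeric(1))
  ids <- key_couplet_ids(key)
  sizes <- vapply(ids, function(id) length(subtree_occurrences(key, id)),
                  numeric(1))
  names(sizes) <- as.character(ids)
  list(min_depth = min(depths), max_depth = max(depths),
       mean_depth = mean(depths), expected_couplets = mean(depths),
       depths = depths, subtree_sizes = sizes)
}
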