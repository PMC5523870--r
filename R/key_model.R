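# Domain types: characters, taxon occurrences, leads, couplets, keys,
# and structural validation of the couplet graph.

#' Define a character of the ontology
#'
#' @param char_id short unique identifier (used in predicates and
#'   observation files).
#' @param label human-readable name.
#' @param kind one of `"binary"`, `"categorical"`, `"ordinal"`,
#'   `"quantitative"`.  Binary characters have implicit states
#'   `present`/`absent`; ordinal states are ordered as given.
#' @param states state names (categorical/ordinal; at least two).
#' @param units measurement unit for quantitative characters (`""` for an
#'   explicitly unitless count).
#' @param symbol optional short abbreviation (e.g. a figure-legend symbol).
#' @param description free text.
#' @return a list of class `dk_character`.
#' @export
dk_character <- function(char_id, label = char_id,
                         kind = c("binary", "categorical", "ordinal",
                                  "quantitative"),
                         states = NULL, units = NA_character_,
                         symbol = "", description = "") {
  kind <- match.arg(kind)
  if (kind %in% c("categorical", "ordinal")) {
    if (is.null(states) || length(states) < 2L)
      stop(sprintf("character '%s': %s characters need >= 2 states",
                   char_id, kind), call. = FALSE)
  } else if (kind == "binary") {
    states <- c("present", "absent")
  } else {
    states <- NULL
    if (is.na(units))
      stop(sprintf("character '%s': quantitative characters need units ('%s' for unitless)",
                   char_id, ""), call. = FALSE)
  }
  structure(list(char_id = char_id, label = label, kind = kind,
                 states = states, units = units, symbol = symbol,
                 description = description),
            class = "dk_character")
}

character_states <- function(ch) {
  if (ch$kind == "binary") c("present", "absent") else ch$states
}

# accept a key or a bare named list of dk_character
as_ontology <- function(x) {
  if (inherits(x, "dichokey_key")) return(x$characters)
  x
}

new_ontology <- function(chars) {
  ids <- vapply(chars, `[[`, character(1), "char_id")
  if (anyDuplicated(ids))
    stop("duplicate char_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  names(chars) <- ids
  chars
}

# ---- taxon occurrences ----------------------------------------------------

#' Construct a taxon occurrence (a terminal of a key)
#'
#' `name` is the canonical species or subspecies name (e.g. `"S. macrocarpa"`
#' or `"S. graminifolia subsp. cabraliensis"`); `form` an optional
#' occurrence qualifier such as `"high elevation form"` (not a distinct
#' taxon); `idx` distinguishes multiple terminals of the same taxon.
#'
#' @param name canonical name.
#' @param form optional form qualifier (`""` if none).
#' @param idx occurrence index (positive integer).
#' @return a list of class `dk_occurrence`.
#' @export
dk_occurrence <- function(name, form = "", idx = 1L) {
  stopifnot(nzchar(name), idx >= 1L)
  structure(list(name = name, form = form, idx = as.integer(idx)),
            class = "dk_occurrence")
}

# canonical display label, e.g. "S. harleyi (high elevation form)#2"
occ_label <- function(occ, with_idx = TRUE) {
  lbl <- occ$name
  if (nzchar(occ$form)) lbl <- paste0(lbl, " (", occ$form, ")")
  if (with_idx) lbl <- paste0(lbl, "#", occ$idx)
  lbl
}

# full-name key (without occurrence index): name + form
occ_fullname <- function(occ) occ_label(occ, with_idx = FALSE)

# species name: strip any infraspecific part
species_of <- function(name) sub(" subsp\\. .*$", "", name)

# taxon-level grouping: species, except non-autonym subspecies kept separate
taxon_of <- function(name) {
  if (grepl(" subsp\\. ", name)) {
    parts <- strsplit(name, " subsp\\. ")[[1]]
    sp_epithet <- sub("^.* ", "", parts[1])
    if (identical(parts[2], sp_epithet)) parts[1] else name
  } else name
}

is_subspecies <- function(name) grepl(" subsp\\. ", name)

# target rendering: "C:<int>" or "T:<name>[|form][#k]"
format_target <- function(target) {
  if (target$kind == "couplet") return(paste0("C:", target$couplet))
  occ <- target$occurrence
  t <- paste0("T:", occ$name)
  if (nzchar(occ$form)) t <- paste0(t, "|", occ$form)
  paste0(t, "#", occ$idx)
}

parse_target <- function(text) {
  if (grepl("^C:\\d+$", text))
    return(list(kind = "couplet", couplet = as.integer(sub("^C:", "", text))))
  if (!startsWith(text, "T:"))
    stop(sprintf("malformed target \"%s\" (want C:<int> or T:<name>[|form][#k])",
                 text), call. = FALSE)
  body <- sub("^T:", "", text)
  idx <- 1L
  m <- regexpr("#\\d+$", body)
  if (m != -1L) {
    idx <- as.integer(sub("#", "", regmatches(body, m)))
    body <- sub("#\\d+$", "", body)
  }
  parts <- strsplit(body, "|", fixed = TRUE)[[1]]
  form <- if (length(parts) > 1L) parts[2] else ""
  list(kind = "taxon", occurrence = dk_occurrence(parts[1], form, idx))
}

# ---- leads, couplets, keys ------------------------------------------------

new_lead <- function(couplet_id, slot, statement, clauses, target) {
  stopifnot(slot %in% c("a", "b"))
  structure(list(couplet = as.integer(couplet_id), slot = slot,
                 statement = statement, clauses = clauses, target = target),
            class = "dk_lead")
}

new_key <- function(characters, couplets, root, metadata = list()) {
  structure(list(characters = characters, couplets = couplets,
                 root = as.integer(root), metadata = metadata),
            class = "dichokey_key")
}

key_couplet_ids <- function(key) sort(as.integer(names(key$couplets)))

key_leads <- function(key) {
  out <- list()
  for (id in key_couplet_ids(key))
    for (slot in c("a", "b")) {
      ld <- key$couplets[[as.character(id)]]$leads[[slot]]
      if (!is.null(ld)) out[[length(out) + 1L]] <- ld
    }
  out
}

key_terminal_leads <- function(key) {
  Filter(function(ld) ld$target$kind == "taxon", key_leads(key))
}

key_occurrences <- function(key) {
  lapply(key_terminal_leads(key), function(ld) ld$target$occurrence)
}

#' @export
print.dichokey_key <- function(x, ...) {
  occs <- key_occurrences(x)
  cat(sprintf("Dichotomous key: %d couplets, %d terminal occurrences, %d species\n",
              length(x$couplets), length(occs),
              length(unique(vapply(occs, function(o) species_of(o$name),
                                   character(1))))))
  if (!is.null(x$metadata$title)) cat("  ", x$metadata$title, "\n", sep = "")
  cat(sprintf("  characters: %d; root couplet: %d\n",
              length(x$characters), x$root))
  invisible(x)
}

# ---- validation -----------------------------------------------------------

# can the two leads of a couplet both be satisfied?  exclusive when some
# character carries disjoint single-character constraints, or when every
# disjunct of some clause of one lead is contradicted by the other lead.
leads_mutually_exclusive <- function(lead_a, lead_b, ontology) {
  ca <- clauses_to_constraints(lead_a$clauses, ontology)
  cb <- clauses_to_constraints(lead_b$clauses, ontology)
  shared <- intersect(names(ca$per_char), names(cb$per_char))
  for (ch in shared) {
    if (constraint_is_empty(constraint_intersect(ca$per_char[[ch]],
                                                 cb$per_char[[ch]], ontology)))
      return(TRUE)
  }
  contradicted_by <- function(disj, other_per_char) {
    ch <- disj$char_id
    oc <- other_per_char[[ch]]
    if (is.null(oc)) return(FALSE)
    pc <- pred_constraint(disj, ontology)
    constraint_is_empty(constraint_intersect(pc, oc, ontology))
  }
  for (cl in lead_a$clauses)
    if (all(vapply(cl, contradicted_by, logical(1), other_per_char = cb$per_char)))
      return(TRUE)
  for (cl in lead_b$clauses)
    if (all(vapply(cl, contradicted_by, logical(1), other_per_char = ca$per_char)))
      return(TRUE)
  FALSE
}

#' Validate the structure of a key
#'
#' Checks that the couplet graph is a rooted binary tree: every couplet has
#' exactly two leads, every couplet except the root is the target of exactly
#' one lead, all couplets are reachable from the root and no reference
#' dangles or cycles.  Warnings flag taxa with multiple terminals, couplets
#' whose two leads are not mutually exclusive on any shared character, and
#' couplets whose two leads name the same occurrence.
#'
#' @param key a `dichokey_key`.
#' @return a list of class `dk_validation` with `errors`, `warnings` (each a
#'   data.frame `code`, `location`, `message`) and `stats` (couplets, leads,
#'   terminal_leads, species, multi_entry_species, ...).
#' @examples
#' key <- load_fixture("syagrus_key")
#' rep <- validate_key(key)
#' rep$stats$couplets      # 71
#' rep$stats$terminal_leads  # 72
#' @export
validate_key <- function(key) {
  errors <- list(); warnings <- list()
  err <- function(code, location, message)
    errors[[length(errors) + 1L]] <<- data.frame(code = code,
      location = location, message = message)
  wrn <- function(code, location, message)
    warnings[[length(warnings) + 1L]] <<- data.frame(code = code,
      location = location, message = message)

  ids <- key_couplet_ids(key)
  if (!key$root %in% ids)
    err("missing_root", "key", sprintf("root couplet %d not present", key$root))

  referenced <- integer(0)
  for (id in ids) {
    cp <- key$couplets[[as.character(id)]]
    slots <- names(cp$leads)
    if (!setequal(slots, c("a", "b")))
      err("lead_count", paste0("couplet ", id),
          sprintf("couplet %d has %d lead(s); a dichotomous couplet needs exactly 2",
                  id, length(cp$leads)))
    for (slot in slots) {
      ld <- cp$leads[[slot]]
      tg <- ld$target
      if (tg$kind == "couplet") {
        if (tg$couplet == id)
          err("self_reference", paste0("couplet ", id, slot),
              sprintf("lead %d%s targets its own couplet", id, slot))
        else if (!tg$couplet %in% ids)
          err("dangling_reference", paste0("couplet ", id, slot),
              sprintf("lead %d%s targets missing couplet %d", id, slot, tg$couplet))
        else referenced <- c(referenced, tg$couplet)
      }
    }
    if (setequal(slots, c("a", "b"))) {
      ta <- cp$leads$a$target; tb <- cp$leads$b$target
      if (ta$kind == "taxon" && tb$kind == "taxon" &&
          occ_label(ta$occurrence) == occ_label(tb$occurrence))
        wrn("same_target", paste0("couplet ", id),
            sprintf("both leads of couplet %d name occurrence %s",
                    id, occ_label(ta$occurrence)))
      if (!leads_mutually_exclusive(cp$leads$a, cp$leads$b, key$characters))
        wrn("non_exclusive_leads", paste0("couplet ", id),
            sprintf("leads of couplet %d share no character with mutually exclusive constraints",
                    id))
    }
  }
  dup <- unique(referenced[duplicated(referenced)])
  for (d in dup)
    err("multiply_referenced", paste0("couplet ", d),
        sprintf("couplet %d is the target of more than one lead", d))
  if (key$root %in% referenced)
    err("root_referenced", paste0("couplet ", key$root),
        sprintf("root couplet %d is itself a lead target", key$root))
  orphan <- setdiff(ids, c(referenced, key$root))
  for (o in orphan)
    err("unreachable", paste0("couplet ", o),
        sprintf("couplet %d is referenced by no lead and is not the root", o))

  # cycle / reachability check by traversal from root
  if (key$root %in% ids) {
    seen <- integer(0)
    stack <- key$root
    cyclic <- FALSE
    while (length(stack)) {
      id <- stack[[1]]; stack <- stack[-1]
      if (id %in% seen) { cyclic <- TRUE; break }
      seen <- c(seen, id)
      cp <- key$couplets[[as.character(id)]]
      for (ld in cp$leads)
        if (ld$target$kind == "couplet" && ld$target$couplet %in% ids)
          stack <- c(stack, ld$target$couplet)
    }
    if (cyclic)
      err("cycle", "key", "couplet graph contains a cycle")
    unreachable <- setdiff(ids, seen)
    for (u in setdiff(unreachable, orphan))
      err("unreachable", paste0("couplet ", u),
          sprintf("couplet %d is not reachable from the root", u))
  }

  occs <- key_occurrences(key)
  fullnames <- vapply(occs, occ_fullname, character(1))
  occ_ids <- vapply(occs, occ_label, character(1))
  for (d in unique(occ_ids[duplicated(occ_ids)]))
    err("duplicate_occurrence", d,
        sprintf("occurrence label %s used by more than one terminal lead", d))
  species <- vapply(occs, function(o) species_of(o$name), character(1))
  # multiple entries of the same taxon (forms merged, subspecies separate)
  tx_counts <- table(vapply(occs, function(o) taxon_of(o$name), character(1)))
  multi <- sort(unique(species_of(names(tx_counts[tx_counts > 1L]))))
  for (m in multi)
    wrn("multi_entry_taxon", m,
        sprintf("taxon %s has %d terminal occurrences", m,
                sum(tx_counts[species_of(names(tx_counts)) == m])))

  bindrows <- function(lst) if (length(lst)) do.call(rbind, lst) else
    data.frame(code = character(0), location = character(0),
               message = character(0))
  structure(list(
    errors = bindrows(errors),
    warnings = bindrows(warnings),
    stats = list(
      couplets = length(key$couplets),
      leads = length(key_leads(key)),
      terminal_leads = length(occs),
      occurrences = length(occs),
      species = length(unique(species)),
      subspecies = length(unique(fullnames[vapply(occs, function(o)
        is_subspecies(o$name) && !identical(taxon_of(o$name),
                                            species_of(o$name)), logical(1))])),
      multi_entry_species = multi)),
    class = "dk_validation")
}

#' @export
print.dk_validation <- function(x, ...) {
  cat(sprintf("Key validation: %d error(s), %d warning(s)\n",
              nrow(x$errors), nrow(x$warnings)))
  cat(sprintf("  couplets: %d  leads: %d  terminals: %d  species: %d  subspecies: %d\n",
              x$stats$couplets, x$stats$leads, x$stats$terminal_leads,
              x$stats$species, x$stats$subspecies))
  if (length(x$stats$multi_entry_species))
    cat("  multi-entry species:", paste(x$stats$multi_entry_species,
                                        collapse = ", "), "\n")
  if (nrow(x$errors)) {
    cat("Errors:\n")
    for (i in seq_len(nrow(x$errors)))
      cat(sprintf("  [%s] %s: %s\n", x$errors$code[i], x$errors$location[i],
                  x$errors$message[i]))
  }
  invisible(x)
}

#' List the taxa of a key
#'
#' @param key a `dichokey_key`.
#' @param mode `"occurrences"` returns every terminal occurrence label;
#'   `"species"` collapses subspecies, forms and repeated occurrences to
#'   distinct species names; `"all_terminals"` returns distinct taxon-level
#'   names (species plus non-autonym subspecies, forms merged).
#' @return a sorted character vector.
#' @examples
#' key <- load_fixture("syagrus_key")
#' length(key_taxa(key, "species"))      # 65
#' length(key_taxa(key, "occurrences"))  # 72
#' @export
key_taxa <- function(key, mode = c("occurrences", "species", "all_terminals")) {
  mode <- match.arg(mode)
  occs <- key_occurrences(key)
  out <- switch(mode,
    occurrences = vapply(occs, occ_label, character(1)),
    species = unique(vapply(occs, function(o) species_of(o$name), character(1))),
    all_terminals = unique(vapply(occs, function(o) taxon_of(o$name),
                                  character(1))))
  sort(out, method = "radix")
}
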