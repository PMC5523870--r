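# Readers and writers: the two-file key format (characters.tsv + key.tsv),
# observation / clade / region tables, and Newick export.
#
# characters.tsv: char_id  label  kind  states  units  symbol  description
#   (states comma-separated, in order for ordinal characters; units empty
#   for non-quantitative, "1" may be used for an explicitly unitless count)
# key.tsv:        couplet  slot  statement  predicates  target
#   (slot a/b; predicates in the mini-DSL of parse_predicates(); target
#   "C:<int>" or "T:<canonical name>[|form][#k]")
# Lines starting with "#" are skipped; "#! field: value" lines carry
# key metadata (title, source) and are round-tripped.

read_tsv_lines <- function(text) {
  lines <- if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    readLines(text, encoding = "UTF-8")
  else strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  meta <- list()
  for (ln in grep("^#! ", lines, value = TRUE)) {
    m <- regmatches(ln, regexec("^#! *([^:]+): *(.*)$", ln))[[1]]
    if (length(m) == 3L) meta[[trimws(m[2])]] <- m[3]
  }
  list(lines = lines[!startsWith(lines, "#")], meta = meta)
}

parse_tsv <- function(lines, n_cols, what) {
  lines <- lines[nzchar(trimws(lines))]
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) != n_cols)
    stop(sprintf("%s: expected %d columns, found %d in header", what, n_cols,
                 length(header)), call. = FALSE)
  if (length(lines) < 2L) {
    tab <- as.data.frame(matrix(character(0), ncol = n_cols,
                                dimnames = list(NULL, header)),
                         stringsAsFactors = FALSE)
    return(tab)
  }
  rows <- lapply(seq_along(lines)[-1], function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    length(f) <- n_cols                      # pad trailing empties
    f[is.na(f)] <- ""
    if (length(strsplit(lines[i], "\t", fixed = TRUE)[[1]]) > n_cols)
      stop(sprintf("%s: malformed row %d (too many columns)", what, i),
           call. = FALSE)
    f
  })
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(tab) <- header
  tab
}

#' Parse a key from its two source texts
#'
#' @param characters_text contents (or path) of `characters.tsv`.
#' @param couplets_text contents (or path) of `key.tsv`.
#' @return a `dichokey_key`.
#' @seealso [read_key()], [write_key()], [load_fixture()]
#' @export
parse_key <- function(characters_text, couplets_text) {
  cdoc <- read_tsv_lines(characters_text)
  ctab <- parse_tsv(cdoc$lines, 7L, "characters.tsv")
  chars <- lapply(seq_len(nrow(ctab)), function(i) {
    states <- trimws(strsplit(ctab$states[i], ",", fixed = TRUE)[[1]])
    states <- states[nzchar(states)]
    dk_character(ctab$char_id[i], ctab$label[i], ctab$kind[i],
                 states = if (length(states)) states else NULL,
                 units = if (ctab$kind[i] == "quantitative") ctab$units[i]
                         else NA_character_,
                 symbol = ctab$symbol[i], description = ctab$description[i])
  })
  ontology <- new_ontology(chars)

  kdoc <- read_tsv_lines(couplets_text)
  ktab <- parse_tsv(kdoc$lines, 5L, "key.tsv")
  seen <- character(0)
  couplets <- list()
  for (i in seq_len(nrow(ktab))) {
    id <- suppressWarnings(as.integer(ktab$couplet[i]))
    slot <- ktab$slot[i]
    if (is.na(id) || id < 1L || !slot %in% c("a", "b"))
      stop(sprintf("key.tsv row %d: bad couplet/slot \"%s\"/\"%s\"",
                   i, ktab$couplet[i], slot), call. = FALSE)
    keyid <- paste0(id, slot)
    if (keyid %in% seen)
      stop(sprintf("duplicate lead %d%s in key.tsv", id, slot), call. = FALSE)
    seen <- c(seen, keyid)
    clauses <- parse_predicates(ktab$predicates[i], ontology)
    lead <- new_lead(id, slot, ktab$statement[i], clauses,
                     parse_target(ktab$target[i]))
    cid <- as.character(id)
    if (is.null(couplets[[cid]])) couplets[[cid]] <- list(id = id, leads = list())
    couplets[[cid]]$leads[[slot]] <- lead
  }
  ids <- sort(as.integer(names(couplets)))
  referenced <- unlist(lapply(couplets, function(cp)
    lapply(cp$leads, function(ld)
      if (ld$target$kind == "couplet") ld$target$couplet else NULL)))
  root <- setdiff(ids, referenced)
  root <- if (length(root)) min(root) else ids[1]
  new_key(ontology, couplets, root, kdoc$meta)
}

#' Read a key from a pair of files
#'
#' @param characters_file path to `characters.tsv`.
#' @param couplets_file path to `key.tsv`.
#' @return a `dichokey_key`.
#' @export
read_key <- function(characters_file, couplets_file) {
  parse_key(characters_file, couplets_file)
}

#' Write a key back to its canonical two-file form
#'
#' Canonicalisation: metadata lines first, couplets in numeric order with
#' slot a before b, characters in ontology order, predicates re-rendered by
#' [render_predicates()].  `parse_key()` of the output is structurally equal
#' to the input, and writing is byte-stable.
#'
#' @param key a `dichokey_key`.
#' @param characters_file,couplets_file optional output paths.
#' @return list with `characters_text` and `couplets_text`.
#' @export
write_key <- function(key, characters_file = NULL, couplets_file = NULL) {
  ctab <- c("char_id\tlabel\tkind\tstates\tunits\tsymbol\tdescription",
    vapply(key$characters, function(ch)
      paste(ch$char_id, ch$label, ch$kind,
            if (ch$kind %in% c("categorical", "ordinal"))
              paste(ch$states, collapse = ",") else "",
            if (ch$kind == "quantitative") ch$units else "",
            ch$symbol, ch$description, sep = "\t"),
      character(1)))
  meta <- vapply(names(key$metadata), function(f)
    sprintf("#! %s: %s", f, key$metadata[[f]]), character(1))
  ktab <- "couplet\tslot\tstatement\tpredicates\ttarget"
  for (id in key_couplet_ids(key)) for (slot in c("a", "b")) {
    ld <- key$couplets[[as.character(id)]]$leads[[slot]]
    ktab <- c(ktab, paste(id, slot, ld$statement,
                          render_predicates(ld$clauses),
                          format_target(ld$target), sep = "\t"))
  }
  characters_text <- paste0(paste(ctab, collapse = "\n"), "\n")
  couplets_text <- paste0(paste(c(meta, ktab), collapse = "\n"), "\n")
  if (!is.null(characters_file))
    writeLines(characters_text, characters_file, sep = "", useBytes = TRUE)
  if (!is.null(couplets_file))
    writeLines(couplets_text, couplets_file, sep = "", useBytes = TRUE)
  invisible(list(characters_text = characters_text,
                 couplets_text = couplets_text))
}

newick_label <- function(x) {
  x <- gsub("[^A-Za-z0-9#.-]+", "_", x)
  gsub("_+", "_", x)
}

#' Export the couplet tree as Newick
#'
#' Internal nodes are labelled `c<id>`, leaves carry the sanitised canonical
#' occurrence label with a `#k` disambiguator, and every branch has length 1.
#' The output is parseable by standard Newick parsers (e.g.
#' `ape::read.tree`), with the same topology as the couplet graph.
#'
#' @param key a valid `dichokey_key`.
#' @param file optional output path.
#' @return the Newick string.
#' @examples
#' key <- load_fixture("syagrus_key")
#' nw <- export_newick(key)
#' @export
export_newick <- function(key, file = NULL) {
  build <- function(ld) {
    if (ld$target$kind == "taxon")
      return(paste0(newick_label(occ_label(ld$target$occurrence)), ":1"))
    id <- ld$target$couplet
    cp <- key$couplets[[as.character(id)]]
    paste0("(", build(cp$leads$a), ",", build(cp$leads$b), ")c", id, ":1")
  }
  cp <- key$couplets[[as.character(key$root)]]
  txt <- paste0("(", build(cp$leads$a), ",", build(cp$leads$b), ")c",
                key$root, ";")
  if (!is.null(file)) writeLines(txt, file)
  txt
}

#' Read an observation file
#'
#' Two tab-separated columns `char_id` and `value`; `"?"` marks an explicit
#' unknown (kept as `NA`).
#'
#' @param file path (or the text itself).
#' @param ontology optional ontology (or key) for type checking.
#' @return named list of values.
#' @export
read_observations <- function(file, ontology = NULL) {
  doc <- read_tsv_lines(file)
  tab <- parse_tsv(doc$lines, 2L, "observations.tsv")
  obs <- stats::setNames(as.list(tab$value), tab$char_id)
  obs <- lapply(obs, function(v) if (identical(v, "?")) NA else v)
  if (!is.null(ontology)) obs <- check_observation(obs, as_ontology(ontology))
  obs
}

normalize_clade_label <- function(x) {
  x <- trimws(sub("/.*$", "", x))
  x[x == "Clustered stemmed"] <- "Cluster stemmed"
  x
}

#' Read a reference clade table
#'
#' Columns: `clade` (label as printed), `branch` (key-branch label the row
#' was compared with, may be empty), `taxon`, `analyzed` (1 = member of the
#' molecular clade itself), `in_branch` (1 = listed in the similar key
#' branch).  Clade labels are normalised (suffixes after `/` stripped) into
#' column `clade`, with the printed label kept as `clade_raw`.  When a key
#' is supplied, taxa not matching any key taxon are reported in attribute
#' `"unmatched"`.
#'
#' @param file path or text.
#' @param key optional `dichokey_key` to resolve names against.
#' @return a data.frame.
#' @export
read_clades <- function(file, key = NULL) {
  doc <- read_tsv_lines(file)
  tab <- parse_tsv(doc$lines, 5L, "clades.tsv")
  tab$analyzed <- as.integer(tab$analyzed)
  tab$in_branch <- as.integer(tab$in_branch)
  tab$clade_raw <- tab$clade
  tab$clade <- normalize_clade_label(tab$clade_raw)
  if (!is.null(key)) {
    known <- key_taxa(key, "species")
    attr(tab, "unmatched") <- sort(setdiff(unique(tab$taxon), known))
  }
  tab
}

#' Read a taxon-region table
#'
#' Columns: `taxon`, `region_codes` (comma-separated region names/codes).
#'
#' @param file path or text.
#' @param key optional key; species absent from the table are reported in
#'   attribute `"missing"`.
#' @return a data.frame with columns `taxon` and `region_codes`.
#' @export
read_regions <- function(file, key = NULL) {
  doc <- read_tsv_lines(file)
  tab <- parse_tsv(doc$lines, 2L, "regions.tsv")
  if (!is.null(key))
    attr(tab, "missing") <- sort(setdiff(key_taxa(key, "species"), tab$taxon))
  tab
}

region_set <- function(regions, taxon) {
  hit <- regions$region_codes[regions$taxon == taxon]
  if (length(hit) == 0L) return(character(0))
  sort(unique(trimws(unlist(strsplit(hit, ",", fixed = TRUE)))))
}
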