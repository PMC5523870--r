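# Packaged Syagrus fixture loader and the seeded random-key generator used
# for property-based testing.

#' Load a packaged fixture
#'
#' `"syagrus_key"` is the complete 71-couplet anatomical key to the palm
#' genus Syagrus (leaflet margin anatomy; 72 terminal occurrences, 65
#' species and two non-autonym subspecies); `"clades"` the reference
#' molecular-clade table; `"regions"` the taxon-region table.  Transcription
#' notes ship alongside the TSV files and are attached as attribute
#' `"notes"`.
#'
#' @param name one of `"syagrus_key"`, `"clades"`, `"regions"`.
#' @return a `dichokey_key` or data.frame.
#' @export
load_fixture <- function(name = c("syagrus_key", "clades", "regions")) {
  name <- match.arg(name)
  dir <- system.file("extdata", "syagrus", package = "dichokey",
                     mustWork = TRUE)
  notes <- readLines(file.path(dir, "NOTES.md"), encoding = "UTF-8")
  obj <- switch(name,
    syagrus_key = read_key(file.path(dir, "characters.tsv"),
                           file.path(dir, "key.tsv")),
    clades = read_clades(file.path(dir, "clades.tsv"),
                         key = load_fixture("syagrus_key")),
    regions = read_regions(file.path(dir, "regions.tsv"),
                           key = load_fixture("syagrus_key")))
  attr(obj, "notes") <- notes
  obj
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a random dichotomous key with known ground truth
#'
#' Builds a rooted binary key over `n_taxa` terminals (`n_taxa - 1`
#' couplets).  Every couplet splits on a single character with mutually
#' exclusive predicates (disjoint state sets, or a numeric threshold), and
#' a character is never reused along one root-to-terminal path, so every
#' path is consistent.  Split sizes are biased toward balance; `skew`
#' widens the random split range (larger values exercise deeper chains).
#' The returned truth table holds, for every taxon, one value per character
#' that satisfies exactly its own path.
#'
#' @param n_taxa number of terminals (>= 2).
#' @param n_characters ontology size; must be at least
#'   `ceiling(log2(n_taxa))` so that balanced paths fit.
#' @param seed integer seed; the same seed reproduces the bundle exactly.
#' @param skew split-imbalance half-width in `[0, 0.5)`.
#' @param p_quant probability that a character is quantitative.
#' @return a list of class `dk_synth_bundle`: `key` (a `dichokey_key`),
#'   `truth` (data.frame, one row per taxon), `params`.
#' @examples
#' b <- generate_key(8, 5, seed = 42)
#' validate_key(b$key)$stats$couplets   # 7
#' @export
generate_key <- function(n_taxa, n_characters, seed, skew = 0.2,
                         p_quant = 0.3) {
  stopifnot(n_taxa >= 2L)
  need <- ceiling(log2(n_taxa))
  if (n_characters < need)
    stop(sprintf("insufficient characters to discriminate %d taxa (need >= %d)",
                 n_taxa, need), call. = FALSE)
  with_seed(seed, {
    char_ids <- sprintf("char%02d", seq_len(n_characters))
    chars <- lapply(char_ids, function(id) {
      if (stats::runif(1) < p_quant)
        dk_character(id, paste("measurement", id), "quantitative", units = "mm")
      else {
        k <- sample(2:4, 1)
        dk_character(id, paste("state of", id), "categorical",
                     states = paste0("s", seq_len(k)))
      }
    })
    ontology <- new_ontology(chars)
    taxa <- sprintf("taxon_%02d", seq_len(n_taxa))
    truth <- as.data.frame(lapply(ontology, function(ch) {
      if (ch$kind == "quantitative") round(stats::runif(n_taxa, 0, 100), 2)
      else sample(ch$states, n_taxa, replace = TRUE)
    }), stringsAsFactors = FALSE)
    rownames(truth) <- taxa

    couplets <- list()
    next_id <- 0L
    build <- function(members, avail) {
      next_id <<- next_id + 1L
      id <- next_id
      n <- length(members)
      cap <- 2L^(length(avail) - 1L)   # max child size the remaining chars allow
      lo <- max(1L, n - cap); hi <- min(n - 1L, cap)
      k <- round(n * stats::runif(1, 0.5 - skew, 0.5 + skew))
      k <- min(max(k, lo), hi)
      left <- members[seq_len(k)]; right <- members[-seq_len(k)]
      ch_id <- sample(avail, 1L)
      ch <- ontology[[ch_id]]
      if (ch$kind == "quantitative") {
        t <- round(stats::runif(1, 10, 90), 1)
        pa <- new_predicate(ch_id, "lt", t)
        pb <- new_predicate(ch_id, "ge", t)
        truth[left, ch_id] <<- round(t - stats::runif(length(left), 0.5, 9), 2)
        truth[right, ch_id] <<- round(t + stats::runif(length(right), 0, 9), 2)
      } else {
        split_at <- sample(seq_len(length(ch$states) - 1L), 1L)
        sa <- ch$states[seq_len(split_at)]
        sb <- setdiff(ch$states, sa)
        pa <- new_predicate(ch_id, "in_set", sa)
        pb <- new_predicate(ch_id, "in_set", sb)
        truth[left, ch_id] <<- sample(sa, length(left), replace = TRUE)
        truth[right, ch_id] <<- sample(sb, length(right), replace = TRUE)
      }
      mk_lead <- function(slot, pred, sub) {
        clauses <- structure(list(list(pred)), class = "dk_clauses")
        target <- if (length(sub) == 1L)
          list(kind = "taxon", occurrence = dk_occurrence(sub))
        else list(kind = "couplet", couplet = NA_integer_)  # patched below
        new_lead(id, slot, render_predicates(clauses), clauses, target)
      }
      lead_a <- mk_lead("a", pa, left)
      lead_b <- mk_lead("b", pb, right)
      avail2 <- setdiff(avail, ch_id)
      if (length(left) > 1L) lead_a$target$couplet <- build(left, avail2)
      if (length(right) > 1L) lead_b$target$couplet <- build(right, avail2)
      couplets[[as.character(id)]] <<- list(id = id,
                                            leads = list(a = lead_a, b = lead_b))
      id
    }
    build(taxa, char_ids)
    key <- new_key(ontology, couplets, 1L,
                   list(title = sprintf("synthetic key (n=%d, m=%d, seed=%d)",
                                        n_taxa, n_characters, seed),
                        source = "generated"))
    structure(list(key = key, truth = truth,
                   params = list(n_taxa = n_taxa,
                                 n_characters = n_characters, seed = seed,
                                 skew = skew, p_quant = p_quant)),
              class = "dk_synth_bundle")
  })
}

# a taxon's truth row as an observation list
truth_observation <- function(bundle, taxon) {
  stats::setNames(as.list(bundle$truth[taxon, , drop = TRUE]),
                  colnames(bundle$truth))
}
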