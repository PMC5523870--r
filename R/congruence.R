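# Comparing key branches with reference (molecular) clades and geographic
# regions: crown branches, branch purity, region homogeneity.

# species sets below every lead, as a named list "<couplet><'>" -> species
all_branch_species <- function(key) {
  out <- list()
  for (id in key_couplet_ids(key)) for (slot in c("a", "b")) {
    lbl <- format_branch_label(id, slot)
    out[[lbl]] <- branch_membership(key, lbl, "species")
  }
  out
}

branch_depths <- function(key) {
  parents <- key_parents(key)
  depth_of <- function(id) {
    d <- 1L
    cur <- parents[[as.character(id)]]
    while (!is.null(cur)) { d <- d + 1L; cur <- parents[[as.character(cur$couplet)]] }
    d
  }
  ids <- key_couplet_ids(key)
  stats::setNames(vapply(ids, depth_of, integer(1)), as.character(ids))
}

#' Crown branch(es) of a taxon group
#'
#' The deepest lead subtree(s) containing every group member present in the
#' key (membership via any occurrence).  Returns `"ROOT"` when no proper
#' lead contains the whole group; all co-deepest labels are returned,
#' sorted.
#'
#' @param key a valid `dichokey_key`.
#' @param group character vector of species names.
#' @return character vector of branch labels.
#' @examples
#' key <- load_fixture("syagrus_key")
#' crown_branch(key, c("S. itapebiensis", "S. weddelliana",
#'                     "S. hoehnei", "S. insignis"))   # "53"
#' @export
crown_branch <- function(key, group) {
  present <- intersect(group, key_taxa(key, "species"))
  if (length(present) == 0L)
    stop("group has no member in the key", call. = FALSE)
  sets <- all_branch_species(key)
  containing <- names(sets)[vapply(sets, function(s) all(present %in% s),
                                   logical(1))]
  if (length(containing) == 0L) return("ROOT")
  depths <- branch_depths(key)
  d <- depths[sub("'$", "", containing)]
  sort(containing[d == max(d)], method = "radix")
}

#' Precision and recall of a key branch against a taxon group
#'
#' Species-level: precision is the share of branch species that belong to
#' the group, recall the share of in-key group species found in the branch.
#'
#' @param key a valid `dichokey_key`.
#' @param group character vector of species names.
#' @param branch_label a branch label or `"ROOT"`.
#' @return list with `precision`, `recall`, `branch_species`,
#'   `group_in_key`, `overlap`.
#' @export
branch_purity <- function(key, group, branch_label) {
  branch <- branch_membership(key, branch_label, "species")
  in_key <- intersect(group, key_taxa(key, "species"))
  overlap <- intersect(in_key, branch)
  list(precision = if (length(branch)) length(overlap) / length(branch)
                   else NaN,
       recall = if (length(in_key)) length(overlap) / length(in_key)
                else NaN,
       branch_species = branch, group_in_key = sort(in_key),
       overlap = sort(overlap))
}

#' Region homogeneity of a key branch
#'
#' The modal region is the region occurring in the most member region sets
#' (ties broken alphabetically); homogeneity is the fraction of branch
#' species (with region data) whose region set intersects the modal region.
#'
#' @param key a valid `dichokey_key`.
#' @param regions a region table from [read_regions()].
#' @param branch_label a branch label or `"ROOT"`.
#' @return list with `homogeneity` (in `[0, 1]`; `NaN` when no member has
#'   region data), `modal_region`, `members`, `missing` (members without
#'   region data).
#' @export
region_homogeneity <- function(key, regions, branch_label) {
  members <- branch_membership(key, branch_label, "species")
  sets <- lapply(members, function(t) region_set(regions, t))
  names(sets) <- members
  have <- members[vapply(sets, length, integer(1)) > 0]
  if (length(have) == 0L)
    return(list(homogeneity = NaN, modal_region = NA_character_,
                members = members, missing = members))
  counts <- table(unlist(sets[have]))
  modal <- sort(names(counts)[counts == max(counts)], method = "radix")[1]
  hit <- vapply(have, function(t) modal %in% sets[[t]], logical(1))
  list(homogeneity = mean(hit), modal_region = modal, members = members,
       missing = setdiff(members, have))
}

#' Members of a reference clade
#'
#' @param clades a clade table from [read_clades()].
#' @param clade normalised clade label.
#' @param source `"molecular"` (column-2 members, `analyzed == 1`) or
#'   `"branch"` (full similar-branch lists, `in_branch == 1`).
#' @param branch optional branch label to restrict to one table row (a
#'   clade can be compared against several key branches).
#' @return sorted character vector of taxon names.
#' @export
clade_members <- function(clades, clade,
                          source = c("molecular", "branch"), branch = NULL) {
  source <- match.arg(source)
  sel <- clades$clade == clade
  if (!is.null(branch)) sel <- sel & clades$branch == branch
  sel <- sel & (if (source == "molecular") clades$analyzed == 1L
                else clades$in_branch == 1L)
  sort(unique(clades$taxon[sel]), method = "radix")
}

#' Clade-versus-branch congruence report
#'
#' For every (clade, reference branch) row group of the clade table:
#' the crown branch of the clade members, and precision/recall of the
#' tabulated reference branch against them; plus region homogeneity of each
#' reference branch when a region table is given.
#'
#' @param key a valid `dichokey_key`.
#' @param clades clade table ([read_clades()]).
#' @param regions optional region table ([read_regions()]).
#' @param source membership source, see [clade_members()].
#' @return a data.frame with one row per clade/branch pair: `clade`,
#'   `branch`, `n_members`, `crown`, `precision`, `recall`,
#'   `region_homogeneity`.
#' @export
congruence_report <- function(key, clades, regions = NULL,
                              source = c("molecular", "branch")) {
  source <- match.arg(source)
  pairs <- unique(clades[clades$branch != "", c("clade", "branch")])
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    cl <- pairs$clade[i]; br <- pairs$branch[i]
    members <- clade_members(clades, cl, source, branch = br)
    in_key <- intersect(members, key_taxa(key, "species"))
    crown <- if (length(in_key)) paste(crown_branch(key, in_key),
                                       collapse = "+") else NA_character_
    pur <- branch_purity(key, members, br)
    rh <- if (is.null(regions)) NaN
          else region_homogeneity(key, regions, br)$homogeneity
    data.frame(clade = cl, branch = br, n_members = length(members),
               crown = crown, precision = pur$precision, recall = pur$recall,
               region_homogeneity = rh, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
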