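#' @include scan.R promoter-io.R
NULL

#' Map a TSS-relative motif hit onto alignment columns
#'
#' Converts a hit's TSS-relative start position in one species to the columns
#' of the gapped alignment spanned by the hit's first and last ungapped
#' bases. Internal gaps widen the interval, so its width is at least the
#' motif length.
#'
#' @param aligned an [AlignedPromoterSet-class].
#' @param species the hit's species (a member of the alignment).
#' @param position TSS-relative position of the hit's leftmost base.
#' @param k motif length in bases (default 7).
#' @return integer `c(start_col, end_col)`.
#' @export
mapHitToColumns <- function(aligned, species, position, k = 7L) {
  stopifnot(is(aligned, "AlignedPromoterSet"))
  if (!species %in% names(aligned@alignment))
    stop("species not in alignment: ", species)
  u <- aligned@upstream[[species]]; d <- aligned@downstream[[species]]
  start <- tssToIndex(position, u, d)
  if (start + k - 1L > u + d)
    stop("hit extends beyond the aligned span of ", species)
  chars <- strsplit(as.character(aligned@alignment[[species]]), "")[[1]]
  baseCols <- which(chars != "-")
  cols <- baseCols[start:(start + k - 1L)]
  c(cols[1L], cols[k])
}

# shared cluster builder: hits must carry species/position/strand/matched_seq
# plus col_start/col_end intervals; single-linkage by interval overlap.
.buildClusters <- function(hits, allSpecies, m, method) {
  m <- as.integer(m)
  if (nrow(hits) == 0) {
    return(new("ConservedSiteSet",
               clusters = data.frame(cluster_id = integer(),
                                     start_col = integer(), end_col = integer(),
                                     n_species_present = integer(),
                                     conserved = logical(),
                                     present_species = character(),
                                     absent_species = character()),
               members = list(), species = allSpecies, minSpecies = m,
               method = method))
  }
  ord <- order(hits$col_start, hits$col_end, hits$species, hits$position)
  hits <- hits[ord, , drop = FALSE]
  # connected components of the interval-overlap graph via a left-to-right
  # sweep: a new component starts when an interval begins past the running max
  comp <- integer(nrow(hits))
  comp[1] <- 1L
  reach <- hits$col_end[1]
  for (i in seq_len(nrow(hits))[-1]) {
    if (hits$col_start[i] > reach) comp[i] <- comp[i - 1L] + 1L
    else comp[i] <- comp[i - 1L]
    reach <- max(reach, hits$col_end[i])
    if (comp[i] != comp[i - 1L]) reach <- hits$col_end[i]
  }
  members <- list(); rows <- list()
  for (cid in unique(comp)) {
    g <- hits[comp == cid, , drop = FALSE]
    # one representative per species: largest total column overlap with the
    # other species' hits; ties broken by smaller position
    g$representative <- FALSE
    for (sp in unique(g$species)) {
      mine <- which(g$species == sp)
      if (length(mine) == 1L) { g$representative[mine] <- TRUE; next }
      others <- g[g$species != sp, , drop = FALSE]
      score <- vapply(mine, function(i) {
        if (nrow(others) == 0) return(0)
        ov <- pmin(g$col_end[i], others$col_end) -
          pmax(g$col_start[i], others$col_start) + 1L
        sum(pmax(ov, 0L))
      }, numeric(1))
      best <- mine[order(-score, g$position[mine])][1L]
      g$representative[best] <- TRUE
    }
    present <- sort(unique(g$species))
    absent <- sort(setdiff(allSpecies, present))
    rows[[length(rows) + 1L]] <- data.frame(
      cluster_id = length(rows) + 1L,
      start_col = min(g$col_start), end_col = max(g$col_end),
      n_species_present = length(present),
      conserved = length(present) >= m,
      present_species = paste(present, collapse = ","),
      absent_species = paste(absent, collapse = ","),
      stringsAsFactors = FALSE)
    rownames(g) <- NULL
    members[[length(members) + 1L]] <- g
  }
  clusters <- do.call(rbind, rows)
  clusters <- clusters[order(clusters$start_col), , drop = FALSE]
  members <- members[clusters$cluster_id]
  clusters$cluster_id <- seq_len(nrow(clusters))
  rownames(clusters) <- NULL
  new("ConservedSiteSet", clusters = clusters, members = members,
      species = allSpecies, minSpecies = m, method = method)
}

#' Call conserved motif sites across species from an alignment
#'
#' Projects each species' hits into alignment columns
#' ([mapHitToColumns()]) and single-linkage clusters them by column-interval
#' overlap: each connected component of the overlap graph becomes one
#' cluster. Within a cluster at most one hit per species is marked
#' representative (largest column overlap with the other species' hits, ties
#' to the smaller position). A cluster is conserved when at least `m` species
#' are present. Strand is ignored for conservation (a site may lie on
#' opposite strands in different species) but recorded per member.
#'
#' @param hits per-species hit table from [scanSpecies()] (or
#'   [scanPromoter()]); needs columns `species`, `position`, `strand`,
#'   `matched_seq`.
#' @param aligned an [AlignedPromoterSet-class] covering every hit species.
#' @param m minimum number of species for a conserved call; defaults to
#'   all-but-one of the alignment's species.
#' @param k motif length (default 7).
#' @return a [ConservedSiteSet-class].
#' @export
callConserved <- function(hits, aligned, m = length(aligned@alignment) - 1L,
                          k = 7L) {
  stopifnot(is(aligned, "AlignedPromoterSet"))
  allSpecies <- sort(names(aligned@alignment))
  if (m < 2) stop("m must be >= 2")
  extra <- setdiff(unique(hits$species), allSpecies)
  if (length(extra))
    stop("hit species absent from alignment: ", paste(extra, collapse = ", "))
  hits$position <- as.integer(hits$position)
  if (nrow(hits)) {
    iv <- t(vapply(seq_len(nrow(hits)), function(i)
      mapHitToColumns(aligned, hits$species[i], hits$position[i], k = k),
      integer(2)))
    hits$col_start <- iv[, 1]; hits$col_end <- iv[, 2]
  } else {
    hits$col_start <- integer(0); hits$col_end <- integer(0)
  }
  keep <- c("species", "position", "strand", "matched_seq",
            "col_start", "col_end")
  .buildClusters(hits[, keep, drop = FALSE], allSpecies, m, "alignment")
}

#' Cluster hits by TSS position when no alignment is available
#'
#' Fallback conservation caller: hits whose TSS-relative positions differ by
#' at most `toleranceW` bases are single-linkage clustered, with the same
#' cluster contract as [callConserved()]. Cluster columns are reported in TSS
#' position units (`start_col`/`end_col` hold the position range).
#'
#' @param hits per-species hit table (columns `species`, `position`,
#'   `strand`, `matched_seq`).
#' @param toleranceW maximum position difference, in bases (>= 0).
#' @param m minimum species count for a conserved call.
#' @param species the full species universe; defaults to the species seen in
#'   `hits`.
#' @return a [ConservedSiteSet-class].
#' @export
positionalFallback <- function(hits, toleranceW, m,
                               species = sort(unique(hits$species))) {
  if (toleranceW < 0) stop("toleranceW must be >= 0")
  if (m < 2) stop("m must be >= 2")
  hits$position <- as.integer(hits$position)
  # positions as degenerate intervals widened by w/2 on each side implements
  # "differ by <= w" under the overlap sweep; integers only, so widen left
  hits$col_start <- as.integer(hits$position * 2L)
  hits$col_end <- as.integer(hits$position * 2L + 2L * as.integer(toleranceW))
  keep <- c("species", "position", "strand", "matched_seq",
            "col_start", "col_end")
  out <- .buildClusters(hits[, keep, drop = FALSE], sort(species),
                        as.integer(m), "positional")
  # report position ranges, not the doubled sweep coordinates
  fix <- function(mem) {
    mem$col_start <- mem$position; mem$col_end <- mem$position; mem
  }
  out@members <- lapply(out@members, fix)
  out@clusters$start_col <- vapply(out@members, function(g) min(g$position),
                                   integer(1))
  out@clusters$end_col <- vapply(out@members, function(g) max(g$position),
                                 integer(1))
  out
}

#' Write conserved-site clusters as TSV
#'
#' One row per cluster with per-species representative position/strand
#' columns appended.
#'
#' @param x a [ConservedSiteSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeConservedSites <- function(x, path) {
  cl <- x@clusters
  for (sp in x@species) {
    pos <- vapply(x@members, function(g) {
      r <- g[g$representative & g$species == sp, , drop = FALSE]
      if (nrow(r)) sprintf("%d%s", r$position[1], r$strand[1]) else "."
    }, character(1))
    cl[[paste0(sp, "_site")]] <- if (length(pos)) pos else character(0)
  }
  utils::write.table(cl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
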