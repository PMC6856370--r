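#' @include AllClasses.R
NULL

#' Accessors for wreconserve classes
#'
#' `promoterInfo()` returns the per-record metadata of a [PromoterSet-class];
#' `promoterSeqs()` its sequences; `nColumns()` the column count of an
#' [AlignedPromoterSet-class]; `usableSites()` the retained-column count of a
#' [DistanceMatrix-class]; `conservedClusters()`/`clusterMembers()` the summary
#' table and per-cluster members of a [ConservedSiteSet-class].
#'
#' @param x an object of the relevant class.
#' @return see Description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("promoterInfo", function(x) standardGeneric("promoterInfo"))

#' @rdname accessors
#' @export
setGeneric("promoterSeqs", function(x) standardGeneric("promoterSeqs"))

#' @rdname accessors
#' @export
setGeneric("nColumns", function(x) standardGeneric("nColumns"))

#' @rdname accessors
#' @export
setGeneric("usableSites", function(x) standardGeneric("usableSites"))

#' @rdname accessors
#' @export
setGeneric("conservedClusters", function(x) standardGeneric("conservedClusters"))

#' @rdname accessors
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))

#' @rdname accessors
#' @export
setMethod("promoterInfo", "PromoterSet", function(x) x@info)

#' @rdname accessors
#' @export
setMethod("promoterSeqs", "PromoterSet", function(x) x@sequences)

#' @rdname accessors
#' @export
setMethod("nColumns", "AlignedPromoterSet",
          function(x) unique(Biostrings::width(x@alignment)))

#' @rdname accessors
#' @export
setMethod("usableSites", "DistanceMatrix", function(x) x@usableSites)

#' @rdname accessors
#' @export
setMethod("conservedClusters", "ConservedSiteSet", function(x) x@clusters)

#' @rdname accessors
#' @export
setMethod("clusterMembers", "ConservedSiteSet", function(x) x@members)

#' @describeIn PromoterSet number of promoter records
#' @param x a PromoterSet.
#' @export
setMethod("length", "PromoterSet", function(x) length(x@sequences))

#' @describeIn PromoterSet record names (species|gene|isoform)
#' @export
setMethod("names", "PromoterSet", function(x) names(x@sequences))

#' @describeIn PromoterSet subset records
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "PromoterSet", function(x, i, j, ..., drop = TRUE) {
  new("PromoterSet", sequences = x@sequences[i],
      info = x@info[i, , drop = FALSE])
})

setMethod("show", "PromoterSet", function(object) {
  cat("PromoterSet with", length(object), "record(s)\n")
  inf <- object@info
  for (k in seq_len(min(nrow(inf), 8)))
    cat(sprintf("  %s %s [%s] %s: -%d..+%d (%d nt)\n",
                inf$species[k], inf$gene[k], inf$assembly[k], inf$isoform_id[k],
                inf$upstream[k], inf$downstream[k],
                inf$upstream[k] + inf$downstream[k]))
  if (nrow(inf) > 8) cat("  ...\n")
})

setMethod("show", "AlignedPromoterSet", function(object) {
  cat("AlignedPromoterSet:", length(object@alignment), "species x",
      nColumns(object), "columns\n")
  cat(" ", paste(names(object@alignment), collapse = ", "), "\n")
})

setMethod("show", "DegenerateMotif", function(object) {
  cat("DegenerateMotif", object@pattern, "\n")
  cat("  forward:", paste(object@forwardVariants, collapse = " "), "\n")
  cat("  reverse:", paste(object@reverseVariants, collapse = " "), "\n")
})

setMethod("show", "DistanceMatrix", function(object) {
  cat("DistanceMatrix (", object@model, "), ", nrow(object@d), " taxa, ",
      object@usableSites, " usable sites\n", sep = "")
  print(round(object@d, 5))
  if (any(object@saturated)) cat("  (NA entries: saturated pairs)\n")
})

setMethod("show", "ConservedSiteSet", function(object) {
  cat("ConservedSiteSet:", nrow(object@clusters), "cluster(s),",
      sum(object@clusters$conserved), "conserved (m =", object@minSpecies,
      "of", length(object@species), "species;", object@method, "clustering)\n")
  if (nrow(object@clusters)) print(object@clusters)
})

setMethod("show", "ReporterConstruct", function(object) {
  cat(sprintf("ReporterConstruct '%s': window %+d..%+d (%d nt)\n",
              object@name, object@windowFrom, object@windowTo,
              nchar(object@wtSeq)))
  cat(sprintf("  edit at %+d: %s -> %s\n", object@sitePos, object@wtSite,
              object@replacement))
  cat(sprintf("  WT hits: %d, mutant hits: %d\n",
              nrow(object@wtHits), nrow(object@mutHits)))
})

setMethod("show", "SimulationTruth", function(object) {
  cat("SimulationTruth:", object@model, "model, length", object@length,
      "nt, seed", object@seed, "\n")
  if (nrow(object@plantedSites)) {
    cat("  planted sites:\n")
    print(object@plantedSites)
  }
})

#' @describeIn DistanceMatrix distance matrix as a base matrix
#' @param x a DistanceMatrix.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "DistanceMatrix", function(x, ...) x@d)
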