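#' @include conservation.R nj.R reporter.R simulate.R
NULL

.configSchema <- list(
  top = c("seed", "pattern", "upstream", "downstream", "min_species",
          "distance_model", "deletion", "tolerance_w", "species", "inputs",
          "simulate", "reporter", "outdir"),
  inputs = c("promoter_fasta", "manifest", "alignment_fasta",
             "exon_alignment_fasta"),
  simulate = c("length", "planted_sites", "model", "n_isoforms",
               "exon_length", "exon_gap_columns", "exon_n_columns"),
  reporter = c("species", "window", "site", "replacement", "name"),
  species = c("species", "gene", "assembly"))

.checkKeys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop("unknown config key(s) in ", where, ": ", paste(extra, collapse = ", "))
}

#' Validate a pipeline run configuration
#'
#' Strict validation: unknown keys anywhere in the config are rejected, the
#' conservation threshold must not exceed the species count, and either real
#' inputs or a simulation block must be present.
#'
#' @param config a named list (or path to a JSON file) with keys `seed`,
#'   `pattern`, `upstream`, `downstream`, `min_species`, `distance_model`
#'   (`p`/`JC`/`TN93`/`MCL`), `deletion`, `tolerance_w`, `species` (table
#'   with per-species `species`/`gene`/`assembly`, covering e.g. a
#'   per-species ortholog choice such as zebrafish DRD2b), and one of
#'   `inputs` (paths) or `simulate` (generator settings); optional
#'   `reporter` block.
#' @return the normalized config list, invisibly on success.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  .checkKeys(config, .configSchema$top, "top level")
  if (is.null(config$species)) stop("config$species table required")
  sp <- as.data.frame(config$species, stringsAsFactors = FALSE)
  .checkKeys(sp, .configSchema$species, "species table")
  if (is.null(config$min_species)) config$min_species <- nrow(sp) - 1L
  if (config$min_species > nrow(sp))
    stop("min_species (m = ", config$min_species,
         ") exceeds the number of species (", nrow(sp), ")")
  if (is.null(config$pattern)) config$pattern <- "WWCAAAG"
  if (is.null(config$upstream)) config$upstream <- 5000L
  if (is.null(config$downstream)) config$downstream <- 0L
  if (is.null(config$distance_model)) config$distance_model <- "MCL"
  if (is.null(config$deletion)) config$deletion <- "complete"
  if (is.null(config$seed)) config$seed <- 1L
  if (!is.null(config$inputs))
    .checkKeys(config$inputs, .configSchema$inputs, "inputs")
  if (!is.null(config$simulate))
    .checkKeys(config$simulate, .configSchema$simulate, "simulate")
  if (is.null(config$inputs) && is.null(config$simulate))
    stop("config needs either an inputs block or a simulate block")
  if (!is.null(config$reporter))
    .checkKeys(config$reporter, .configSchema$reporter, "reporter")
  config$species <- sp
  invisible(config)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full scan / conserve / tree / design pipeline
#'
#' Executes the stages in order — load or simulate promoters, scan every
#' isoform for the motif, call conserved sites (alignment-based when an
#' alignment is available, positional fallback otherwise), estimate
#' distances and build the NJ tree from the exon alignment, and design the
#' reporter pair if configured — writing each stage's table to `outdir`
#' together with a run manifest (config hash, file checksums, per-stage
#' record counts, seed, package version). Reruns with identical inputs and
#' config produce an identical manifest hash.
#'
#' @param config a config list or JSON path (see [validateConfig()]).
#' @param outdir output directory (created if needed); defaults to
#'   `config$outdir`.
#' @return the manifest list, invisibly; files are written under `outdir`.
#' @export
runPipeline <- function(config, outdir = NULL) {
  config <- validateConfig(config)
  if (is.null(outdir)) outdir <- config$outdir
  if (is.null(outdir)) stop("no output directory given")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  motif <- wreMotif(config$pattern)

  # --- stage: inputs ---------------------------------------------------
  aligned <- NULL; exonAln <- NULL
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    records <- .stage("simulate", {
      ps <- if (!is.null(sim$planted_sites))
        as.data.frame(sim$planted_sites, stringsAsFactors = FALSE) else NULL
      out <- simulatePromoters(
        defaultSpeciesTree(), length = sim$length %||% config$upstream,
        plantedSites = ps, model = sim$model %||% "JC",
        seed = config$seed,
        nIsoforms = sim$n_isoforms %||% 1L, motif = motif)
      aligned <<- out$aligned
      out$records
    })
    exonAln <- .stage("simulate_exons", {
      ex <- simulateExons(defaultExonTree(),
                          length = sim$exon_length %||% 2000L,
                          model = sim$model %||% "JC",
                          seed = config$seed + 1L,
                          gapColumns = sim$exon_gap_columns %||% 0L,
                          nColumns = sim$exon_n_columns %||% 0L)
      ex$alignment
    })
  } else {
    records <- .stage("read_promoters",
                      readPromoterFasta(config$inputs$promoter_fasta,
                                        config$inputs$manifest))
    if (!is.null(config$inputs$alignment_fasta))
      aligned <- .stage("read_alignment",
                        readAlignedFasta(config$inputs$alignment_fasta, records))
    if (!is.null(config$inputs$exon_alignment_fasta))
      exonAln <- .stage("read_exons", {
        a <- Biostrings::readDNAStringSet(config$inputs$exon_alignment_fasta)
        stats::setNames(as.character(a),
                        vapply(strsplit(names(a), "\\s+"), `[`, "", 1L))
      })
  }
  counts$records <- length(records)

  # --- stage: scan -----------------------------------------------------
  hits <- .stage("scan", scanSpecies(records, motif))
  writeHitTable(hits, file.path(outdir, "hits.tsv"))
  counts$hits <- nrow(hits)

  # --- stage: conserve -------------------------------------------------
  cons <- .stage("conserve", {
    if (!is.null(aligned))
      callConserved(hits, aligned, m = config$min_species,
                    k = nchar(config$pattern))
    else positionalFallback(hits, toleranceW = config$tolerance_w %||% 50L,
                            m = config$min_species,
                            species = config$species$species)
  })
  writeConservedSites(cons, file.path(outdir, "conserved_sites.tsv"))
  counts$clusters <- nrow(conservedClusters(cons))
  counts$conserved_clusters <- sum(conservedClusters(cons)$conserved)

  # --- stage: tree -----------------------------------------------------
  tree <- NULL
  if (!is.null(exonAln)) {
    D <- .stage("distances", pairwiseDistances(exonAln,
                                               model = config$distance_model))
    utils::write.table(cbind(taxon = rownames(as.matrix(D)),
                             as.data.frame(as.matrix(D))),
                       file.path(outdir, "distances.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tree <- .stage("nj_tree", njTree(D))
    toNewick(tree, file.path(outdir, "tree.nwk"))
    counts$usable_sites <- usableSites(D)
    counts$sum_branch_lengths <- sumBranchLengths(tree)
  }

  # --- stage: reporter -------------------------------------------------
  if (!is.null(config$reporter)) {
    rp <- config$reporter
    .stage("reporter", {
      idx <- which(promoterInfo(records)$species == rp$species)[1]
      if (is.na(idx)) stop("reporter species not among records: ", rp$species)
      rcon <- designReporter(records, window = unlist(rp$window),
                             sitePos = rp$site,
                             replacement = rp$replacement %||% "CCGCGGT",
                             motif = motif, name = rp$name %||% "reporter",
                             i = idx)
      writeReporter(rcon, file.path(outdir, "reporter.fa"),
                    file.path(outdir, "reporter_edit.json"))
      counts$reporter_wt_hits <- nrow(rcon@wtHits)
      counts$reporter_mut_hits <- nrow(rcon@mutHits)
    })
  }

  # --- manifest --------------------------------------------------------
  cfgFile <- file.path(outdir, "config.json")
  cfg <- config
  cfg$species <- as.data.frame(cfg$species)
  jsonlite::write_json(cfg, cfgFile, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  outputs <- sort(setdiff(list.files(outdir), c("manifest.json")))
  sums <- tools::md5sum(file.path(outdir, outputs))
  names(sums) <- outputs
  manifest <- list(
    package = "wreconserve",
    version = as.character(utils::packageVersion("wreconserve")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfgFile)),
    files = as.list(sums),
    counts = counts)
  manifest$run_hash <- .hashManifest(manifest)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

.hashManifest <- function(manifest) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(manifest[c("config_md5", "files", "counts",
                                         "seed")],
                              auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
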