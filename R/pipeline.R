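#' Write a complete synthetic study to disk
#'
#' Generates every input the pipeline consumes — genome FASTA, GFF3
#' annotation, probe-map BED, per-array probe TSVs (replicates + mock),
#' planted-truth TSV, a titration CSV and a Cq CSV — plus a ready-to-run
#' pipeline configuration file. All randomness derives from the
#' configuration seed, so reruns are bit-identical.
#'
#' @param dir output directory (created if missing).
#' @param config a [SimConfig-class].
#' @param pwm an [EnergyPWM-class]; defaults to the bundled synthetic
#'   example matrix.
#' @param sites planted-site request data.frame (position, target_kd,
#'   permissive); defaults to [studySites()].
#' @return Invisibly, a list with the generated objects (`genome`, `sites`,
#'   `scans`) and the written file paths.
#' @export
simulateStudy <- function(dir, config = simConfig(), pwm = NULL,
                          sites = studySites(config)) {
  if (is.null(pwm))
    pwm <- readEnergyMatrix(system.file(
      "extdata", "lrpB_energy_matrix_synthetic.tsv",
      package = "ChIPtiling", mustWork = TRUE))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome0 <- generateGenome(config)
  planted <- plantMotifs(genome0, pwm, sites,
                         proteinConc = config@proteinConc)
  genome <- planted$genome
  scans <- simulateChip(genome, planted$sites, config)

  paths <- list(
    genome_fasta = file.path(dir, "genome.fasta"),
    annotation_gff3 = file.path(dir, "annotation.gff3"),
    probe_map_bed = file.path(dir, "probe_map.bed"),
    energy_matrix = file.path(dir, "energy_matrix.tsv"),
    truth_sites = file.path(dir, "truth_sites.tsv"),
    isotherm_csv = file.path(dir, "isotherm.csv"),
    cq_csv = file.path(dir, "cq_table.csv"),
    config = file.path(dir, "pipeline_config.yaml"))
  writeGenomeFasta(genome, paths$genome_fasta)
  writeAnnotationGFF3(genome, paths$annotation_gff3)
  probes1 <- scans[[1L]]@probes
  writeRegionsBed(probes1[probes1$duplicate_index == 1L],
                  paths$probe_map_bed)
  writeEnergyMatrix(pwm, paths$energy_matrix)
  write.table(planted$sites, paths$truth_sites, sep = "\t",
              quote = FALSE, row.names = FALSE)

  scan_paths <- character()
  for (s in scans) {
    sp <- file.path(dir, paste0(s@sampleId, ".tsv"))
    writeProbeTable(s, sp)
    scan_paths[s@sampleId] <- sp
  }

  iso <- simulateIsotherm(63e-9, c(1, 2, 4, 8, 16, 32, 64) * 1e-8,
                          noiseSd = 0.03, seed = config@seed)
  write.csv(data.frame(concentration = iso@concentrations,
                       fraction_bound = iso@fractionBound),
            paths$isotherm_csv, row.names = FALSE)
  cqt <- simulateCqTable(genes = c("targetA", "targetB"),
                         foldChanges = c(0.5, 1), seed = config@seed)
  write.csv(cqt, paths$cq_csv, row.names = FALSE)

  chip_ids <- names(scan_paths)[grep("^chip", names(scan_paths))]
  cfg_lines <- c(
    paste0("genome_fasta: ", paths$genome_fasta),
    paste0("annotation_gff3: ", paths$annotation_gff3),
    paste0("probe_tables: ",
           paste(scan_paths[chip_ids], collapse = ",")),
    paste0("mock_table: ", scan_paths[["mock"]]),
    paste0("energy_matrix_a: ", paths$energy_matrix),
    "y0: 1", "fold_threshold: 2", "kd_threshold: 14e-6",
    "smoothing_halfwidth: 400", "min_probes: 3",
    "upstream_window: 200", "extend_bp: 500", "circular: true",
    paste0("seed: ", config@seed))
  writeLines(cfg_lines, paths$config)

  invisible(list(genome = genome, sites = planted$sites, scans = scans,
                 pwm = pwm, paths = c(paths, as.list(scan_paths))))
}

# parse a flat key: value config file (YAML subset; no dependency needed)
readFlatConfig <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^\\s*([^:]+):\\s*(.*)$", lines))
  bad <- which(vapply(kv, length, integer(1)) != 3L)
  if (length(bad))
    stop("malformed config line ", bad[1L], ": ", lines[bad[1L]])
  out <- lapply(kv, function(m) trimws(m[3L]))
  names(out) <- vapply(kv, function(m) trimws(m[2L]), character(1))
  out
}

cfgNum <- function(cfg, key, default) {
  if (is.null(cfg[[key]])) default else as.numeric(cfg[[key]])
}

#' Run the full analysis pipeline from a configuration file
#'
#' Reads the genome, annotation, probe tables (ChIP replicates plus mock)
#' and energy matrix named in a flat `key: value` configuration file, then
#' normalizes, smooths, calls and combines regions, annotates them, scans
#' for motifs genome-wide and upstream of every gene, and (when a second
#' TF's regions are configured) produces the co-binding table. All inputs
#' are validated before any computation; every missing file is reported at
#' once. Outputs and a parameter log are written to `outDir`; identical
#' configurations produce identical outputs.
#'
#' Recognized keys: `genome_fasta`, `annotation_gff3`, `probe_tables`
#' (comma-separated ChIP replicate TSVs), `mock_table`, `energy_matrix_a`,
#' optional `energy_matrix_b` and `regions_b_bed`, and the thresholds `y0`
#' (default 1), `fold_threshold` (2), `kd_threshold` (14e-6, molar),
#' `smoothing_halfwidth` (400 bp), `min_probes` (3), `max_gap_bp` (twice
#' the probe step), `upstream_window` (200 bp), `extend_bp` (500 bp),
#' `circular` (true), `seed`.
#'
#' @param configFile path to the configuration file.
#' @param outDir output directory; defaults to `out_dir` in the config or
#'   the config file's directory.
#' @return Invisibly, a list with the regions `GRanges`, the annotation
#'   data.frame, motif hits, upstream-scan results, the co-binding table
#'   (or NULL) and the written file paths.
#' @export
runPipeline <- function(configFile, outDir = NULL) {
  cfg <- readFlatConfig(configFile)
  need <- c("genome_fasta", "annotation_gff3", "probe_tables",
            "mock_table", "energy_matrix_a")
  problems <- character()
  missing_keys <- setdiff(need, names(cfg))
  if (length(missing_keys))
    problems <- c(problems, paste("missing config key:", missing_keys))
  chip_paths <- if (!is.null(cfg$probe_tables))
    trimws(strsplit(cfg$probe_tables, ",")[[1L]]) else character()
  file_keys <- c(cfg$genome_fasta, cfg$annotation_gff3, chip_paths,
                 cfg$mock_table, cfg$energy_matrix_a,
                 cfg$energy_matrix_b, cfg$regions_b_bed)
  for (f in file_keys)
    if (!is.null(f) && !file.exists(f))
      problems <- c(problems, paste("input file not found:", f))
  if (length(problems))
    stop("pipeline configuration problems:\n  ",
         paste(problems, collapse = "\n  "))

  if (is.null(outDir))
    outDir <- if (!is.null(cfg$out_dir)) cfg$out_dir else
      dirname(configFile)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  circular <- is.null(cfg$circular) ||
    tolower(cfg$circular) %in% c("true", "yes", "1")
  y0 <- cfgNum(cfg, "y0", 1)
  fold_threshold <- cfgNum(cfg, "fold_threshold", 2)
  kd_threshold <- cfgNum(cfg, "kd_threshold", 14e-6)
  half_width <- cfgNum(cfg, "smoothing_halfwidth", 400)
  min_probes <- cfgNum(cfg, "min_probes", 3)
  upstream_window <- cfgNum(cfg, "upstream_window", 200)
  extend_bp <- cfgNum(cfg, "extend_bp", 500)
  max_gap <- if (is.null(cfg$max_gap_bp)) NULL else
    as.numeric(cfg$max_gap_bp)

  genome <- readGenomeFasta(cfg$genome_fasta, cfg$annotation_gff3,
                            circular = circular)
  L <- genomeLength(genome)
  pwm_a <- readEnergyMatrix(cfg$energy_matrix_a)
  chip <- lapply(seq_along(chip_paths), function(i)
    readProbeTable(chip_paths[i], sprintf("chip_rep%d", i),
                   "chip-replicate"))
  mock <- readProbeTable(cfg$mock_table, "mock", "mock")

  prep <- function(s) smoothScan(normalizeScan(s), half_width,
                                 circular = circular, genomeLength = L)
  chip_sm <- lapply(chip, prep)
  mock_sm <- prep(mock)
  rep_regions <- lapply(chip_sm, callRegions, y0 = y0,
                        minProbes = min_probes, maxGapBp = max_gap,
                        circular = circular, genomeLength = L)
  regions <- combineReplicates(rep_regions, chip_sm, mock_sm,
                               foldThreshold = fold_threshold, y0 = y0)
  annotation <- if (length(regions)) annotatePeaks(regions, genome) else
    data.frame()
  hits <- scanSequence(pwm_a, genome, kdThreshold = kd_threshold)
  upstream <- scanUpstream(pwm_a, genome, windowBp = upstream_window,
                           kdThreshold = kd_threshold)

  cobind <- NULL
  if (!is.null(cfg$regions_b_bed)) {
    set_b <- readRegionsBed(cfg$regions_b_bed)
    pwm_b <- if (!is.null(cfg$energy_matrix_b))
      readEnergyMatrix(cfg$energy_matrix_b) else NULL
    cobind <- overlapRegions(regions, set_b, extendBp = extend_bp)
    if (nrow(cobind)) {
      cobind$motif_a <- vapply(cobind$a_index, function(i)
        motifPresenceFlag(pwm_a, genome, regions[i], kd_threshold),
        logical(1))
      cobind$motif_b <- if (!is.null(pwm_b))
        vapply(cobind$b_index, function(i)
          motifPresenceFlag(pwm_b, genome, set_b[i], kd_threshold),
          logical(1)) else FALSE
      # without in vitro assay data, motif presence stands in for the
      # in vitro flag (documented assumption; override downstream if
      # measurements exist)
      cobind$co_class <- assignCoClass(cobind$motif_a, cobind$motif_a,
                                       cobind$motif_b, cobind$motif_b)
    }
  }

  out <- list(
    regions_bed = file.path(outDir, "regions.bed"),
    regions_tsv = file.path(outDir, "regions_annotated.tsv"),
    motif_bed = file.path(outDir, "motif_hits.bed"),
    upstream_tsv = file.path(outDir, "upstream_best_hits.tsv"),
    log = file.path(outDir, "run_log.txt"))
  if (length(regions)) {
    regions$region_id <- sprintf("region_%03d", seq_along(regions))
    writeRegionsBed(regions, out$regions_bed)
    ann_out <- cbind(region_id = regions$region_id, annotation,
                     fold_enrichment = regions$fold_enrichment)
    write.table(ann_out, out$regions_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (length(hits)) {
    hits$name <- sprintf("motif_%04d", seq_along(hits))
    writeRegionsBed(hits, out$motif_bed)
  }
  write.table(upstream$perGene, out$upstream_tsv, sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(cobind)) {
    out$cobinding_tsv <- file.path(outDir, "cobinding.tsv")
    write.table(cobind, out$cobinding_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  params <- c(y0 = y0, fold_threshold = fold_threshold,
              kd_threshold = kd_threshold,
              smoothing_halfwidth = half_width, min_probes = min_probes,
              upstream_window = upstream_window, extend_bp = extend_bp)
  writeLines(c(
    paste0("ChIPtiling ", as.character(utils::packageVersion("ChIPtiling"))),
    paste0(names(params), " = ",
           vapply(params, function(x) format(x, trim = TRUE),
                  character(1))),
    paste0("seed = ", if (is.null(cfg$seed)) "NA" else cfg$seed),
    paste0("n_regions = ", length(regions)),
    paste0("n_motif_hits = ", length(hits))), out$log)

  invisible(list(regions = regions, annotation = annotation,
                 motifHits = hits, upstream = upstream,
                 cobinding = cobind, files = out))
}
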