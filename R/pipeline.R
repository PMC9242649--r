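# End-to-end orchestration: a declarative config (R list or JSON file)
# drives the sequence stages (conservation scan, fingerprint scoring,
# emission entropy), the structure stages (distograms, aromatic core,
# contacts) and the coupling stage (DCA), writing TSV/JSON outputs and a
# run manifest with input checksums.

#' Run the analysis pipeline from a declarative config
#'
#' The config is a named list (or path to a JSON file) with any of the
#' blocks below; stages run in dependency order and each writes its outputs
#' under `out_dir`:
#' \describe{
#'   \item{msa}{`path` (aligned FASTA), optional `labels` (TSV); enables
#'     the conservation scan (`threshold`, default 0.9), fingerprint
#'     scoring/census (optional `fingerprint` JSON path) and the entropy
#'     scan (`max_gap` 0.5, `pseudocount` 1).}
#'   \item{structures}{`paths` (PDB files), `map` (seq-structure TSV),
#'     optional `min_presence` (0.96); enables the distogram stage.}
#'   \item{aromatic_core}{`structure` (PDB path), `helices` (JSON regions),
#'     optional `chain`, `threshold` (5.0); also runs contact detection
#'     (`threshold_general` 4.0, `threshold_pipi` 5.0, `cross_chain`).}
#'   \item{dca}{`msa` path (or reuse the msa block), `lambda_h`, `lambda_J`
#'     (0.01), `theta` (0.1).}
#' }
#'
#' @param config Named list or path to a JSON config file.
#' @param out_dir Output directory (created if missing).
#' @param dry_run Print the stage plan and return it without running.
#' @return A `run_manifest`: list with package version, config hash, input
#'   checksums, per-stage output paths and collected warnings.
#' @export
run_pipeline <- function(config, out_dir = "trpfinger_out", dry_run = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  known <- c("msa", "structures", "aromatic_core", "dca", "seed")
  bad <- setdiff(names(config), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  stages <- intersect(c("msa", "structures", "aromatic_core", "dca"),
                      names(config))
  if (length(stages) == 0L) stop("config enables no stages")
  plan <- paste0("stage ", seq_along(stages), ": ", stages)
  if (dry_run) {
    cat(paste(plan, collapse = "\n"), "\n")
    return(invisible(plan))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("trpfinger")),
    config_hash = unname(config_md5(config)),
    inputs = character(0), outputs = list(), warnings = character(0),
    seed = config$seed
  )
  note <- function(...) {
    manifest$warnings <<- c(manifest$warnings, paste0(...))
  }
  checksum <- function(path) {
    if (!file.exists(path)) stop("missing input path: ", path)
    manifest$inputs[path] <<- unname(tools::md5sum(path))
  }
  emit <- function(stage, name, path) {
    manifest$outputs[[stage]] <<- c(manifest$outputs[[stage]],
                                    stats::setNames(path, name))
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  if ("msa" %in% stages) {
    cfg <- config$msa
    checksum(cfg$path)
    labels <- NULL
    if (!is.null(cfg$labels)) {
      checksum(cfg$labels)
      labels <- read_labels(cfg$labels)
    }
    m <- withCallingHandlers(
      read_msa(cfg$path, labels = labels),
      warning = function(w) {
        note("msa: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    threshold <- cfg$threshold %||% 0.9
    scan <- conservation_scan(m, threshold = threshold)
    p <- file.path(out_dir, "conservation_scan.tsv")
    utils::write.table(scan, p, sep = "\t", quote = FALSE, row.names = FALSE)
    emit("msa", "conservation_scan", p)
    prof <- column_profiles(m)
    p <- file.path(out_dir, "column_profiles.tsv")
    utils::write.table(prof, p, sep = "\t", quote = FALSE, row.names = FALSE)
    emit("msa", "column_profiles", p)
    fp <- if (!is.null(cfg$fingerprint)) {
      checksum(cfg$fingerprint)
      read_fingerprint(cfg$fingerprint)
    } else fingerprint_default()
    if (max(fp$align_col) <= ncol(m)) {
      scores <- score_msa(m, fp)
      p <- file.path(out_dir, "fingerprint_scores.tsv")
      utils::write.table(scores, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      emit("msa", "fingerprint_scores", p)
      cen <- fingerprint_census(scores)
      p <- file.path(out_dir, "fingerprint_census.tsv")
      utils::write.table(cen, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      emit("msa", "fingerprint_census", p)
    } else {
      note("msa: alignment shorter than fingerprint columns; ",
           "fingerprint stage skipped")
    }
    prof_cols <- select_match_columns(m, cfg$max_gap %||% 0.5)
    ep <- emission_probabilities(m, prof_cols,
                                 pseudocount = cfg$pseudocount %||% 1)
    scan_e <- entropy_scan(ep)
    p <- file.path(out_dir, "entropy_scan.tsv")
    utils::write.table(scan_e, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit("msa", "entropy_scan", p)
    if (!is.null(msa_labels(m))) {
      gp <- gap_pattern_profile(m)
      p <- file.path(out_dir, "gap_pattern.tsv")
      utils::write.table(data.frame(subfamily = rownames(gp), gp,
                                    check.names = FALSE),
                         p, sep = "\t", quote = FALSE, row.names = FALSE)
      emit("msa", "gap_pattern", p)
    }
  }

  if ("structures" %in% stages) {
    cfg <- config$structures
    for (pth in cfg$paths) checksum(pth)
    checksum(cfg$map)
    map <- read_seqstruct_map(cfg$map)
    positions <- map$column
    if (!is.null(config$msa$path)) {
      m <- read_msa(config$msa$path)
      positions <- intersect(
        feature_select_positions(m, cfg$min_presence %||% 0.96),
        map$column)
    }
    mats <- lapply(cfg$paths, function(pth) {
      distance_matrix(read_structure(pth), map, positions)
    })
    dg <- distogram_stats(mats)
    p <- file.path(out_dir, "distogram.tsv")
    write_distogram(dg, p)
    emit("structures", "distogram", p)
  }

  if ("aromatic_core" %in% stages) {
    cfg <- config$aromatic_core
    checksum(cfg$structure)
    checksum(cfg$helices)
    st <- read_structure(cfg$structure)
    regions <- read_regions(cfg$helices)
    helices <- lapply(regions, function(m) regions_to_positions(list(m)))
    ac <- aromatic_core(st, helices, chain = cfg$chain,
                        threshold = cfg$threshold %||% 5.0)
    p <- file.path(out_dir, "facing.tsv")
    utils::write.table(ac$facing, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit("aromatic_core", "facing", p)
    p <- file.path(out_dir, "clusters.json")
    jsonlite::write_json(
      list(threshold = ac$clusters$threshold,
           clusters = ac$clusters$clusters,
           singletons = ac$clusters$singletons,
           pair_distances = ac$pair_distances),
      p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    emit("aromatic_core", "clusters", p)
    contacts <- residue_contacts(
      st, threshold_general = cfg$threshold_general %||% 4.0,
      threshold_pipi = cfg$threshold_pipi %||% 5.0,
      cross_chain = isTRUE(cfg$cross_chain))
    p <- file.path(out_dir, "contacts.tsv")
    utils::write.table(contacts, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit("aromatic_core", "contacts", p)
  }

  if ("dca" %in% stages) {
    cfg <- config$dca
    msa_path <- cfg$msa %||% config$msa$path
    if (is.null(msa_path)) stop("dca stage needs an msa path")
    checksum(msa_path)
    m <- read_msa(msa_path)
    model <- plmdca(m, lambda_h = cfg$lambda_h %||% 0.01,
                    lambda_J = cfg$lambda_J %||% 0.01,
                    theta = cfg$theta %||% 0.1,
                    alphabet = if (is.null(cfg$alphabet)) dca_alphabet()
                               else cfg$alphabet)
    sc <- coupling_scores(model)
    p <- file.path(out_dir, "dca_scores.tsv")
    write_coupling_scores(sc, p)
    emit("dca", "dca_scores", p)
  }

  for (stage in names(manifest$outputs)) {
    missing <- !file.exists(unlist(manifest$outputs[[stage]]))
    if (any(missing)) stop("stage ", stage, " lost output file(s)")
  }
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE)
  manifest$manifest_path <- p
  class(manifest) <- "run_manifest"
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("trpfinger run manifest (package ", x$package_version, ")\n", sep = "")
  cat("  config hash: ", x$config_hash, "\n", sep = "")
  cat("  inputs: ", length(x$inputs), "; stages: ",
      paste(names(x$outputs), collapse = ", "), "\n", sep = "")
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("   - ", w, "\n", sep = "")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable md5 of a config list via its canonical JSON serialisation.
config_md5 <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  tools::md5sum(tmp)
}
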