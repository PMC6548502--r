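## Orchestration: run the stages count -> normalize -> fit -> yield (and
## simulate) from one structured config, with a run manifest and simple
## resumability (a stage is skipped when its outputs are newer than its
## inputs, unless force = TRUE).

.writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.readTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

.stageFresh <- function(outputs, inputs) {
  if (!all(file.exists(outputs))) return(FALSE)
  if (length(inputs) == 0) return(TRUE)
  min(file.mtime(outputs)) >= max(file.mtime(inputs))
}

.runStage <- function(name, outputs, inputs, force, code) {
  if (!force && .stageFresh(outputs, inputs)) {
    message("stage '", name, "': up to date, skipped")
    return(FALSE)
  }
  message("stage '", name, "': running")
  tryCatch(code, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  TRUE
}

#' Run the analysis pipeline from a structured config
#'
#' Executes, in dependency order and with resumability, the stages of a
#' run: \code{simulate} (optional; generates bond counts and a spike-in
#' table with known ground truth), \code{count} (optional; discovers
#' introns in BAM/SAM files and counts bond reads), \code{normalize}
#' (spike-in model fit), \code{fit} (per-bond kinetic fit) and
#' \code{yield} (optional; per-acceptor splicing yield when both
#' first-order site rates and coupled junction rates are available).
#' Every stage writes TSV outputs into \code{out_dir} and the run ends
#' with a \code{manifest.json} recording the package version, seed,
#' thresholds and input checksums.
#'
#' @param config a list, or path to a JSON file, with elements
#'   \code{out_dir}, \code{seed}, and optionally \code{simulate}
#'   (\code{n_bonds}, \code{model}, ...), \code{counts} /\code{spikes}
#'   (input TSV paths when not simulating), \code{bams} + \code{gtf}
#'   (alignment inputs for the count stage), \code{fit}
#'   (\code{model}, \code{min_total_count}, \code{n_starts}).
#' @param force rerun stages even when outputs are current.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config, force = FALSE) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  out <- config$out_dir
  if (is.null(out)) stop("config$out_dir is required")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  if (is.null(seed)) stop("config$seed is required")
  p <- function(f) file.path(out, f)

  design <- if (!is.null(config$design)) {
    d <- .readTsv(config$design); checkDesign(d); d
  } else defaultDesign()
  .writeTsv(design, p("design.tsv"))

  inputs <- character(0)

  ## --- simulate ------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    .runStage("simulate", p(c("counts.tsv", "spikes.tsv", "truth.tsv")),
              character(0), force, {
      cfg <- simulationConfig(n_bonds = sim$n_bonds %||% 200,
                              model = sim$model %||% "first_order",
                              design = design, seed = seed)
      truth <- sampleGroundTruth(cfg)
      counts <- simulateBondCounts(truth, cfg)
      spikes <- simulateSpikeIns(cfg)
      .writeTsv(cbind(bond_id = rownames(counts), as.data.frame(counts)),
                p("counts.tsv"))
      .writeTsv(cbind(spike_id = rownames(spikes$counts),
                      labeled = as.integer(spikes$labeled),
                      as.data.frame(spikes$counts)), p("spikes.tsv"))
      .writeTsv(truth, p("truth.tsv"))
    })
    counts_path <- p("counts.tsv"); spikes_path <- p("spikes.tsv")
  } else {
    counts_path <- config$counts; spikes_path <- config$spikes
  }

  ## --- count (alignment inputs) --------------------------------------
  if (!is.null(config$bams)) {
    .runStage("count", p("introns.bed"), unlist(config$bams), force, {
      introns <- discoverIntrons(config$bams[[1]],
                                 min_split_reads = config$min_split_reads %||% 10,
                                 mapq = config$mapq %||% 255)
      if (!is.null(config$gtf)) {
        ann <- importAnnotation(config$gtf)
        introns <- classifyIntrons(introns, ann)
      }
      writeIntronBed(introns, p("introns.bed"))
      tabs <- lapply(config$bams, countBondReads, introns = introns,
                     mapq = config$mapq %||% 255)
      names(tabs) <- design$sample_id[seq_along(tabs)]
      long <- do.call(rbind, Map(function(t, s)
        cbind(sample_id = s, t), tabs, names(tabs)))
      .writeTsv(long, p("bond_counts.tsv"))
    })
    inputs <- c(inputs, unlist(config$bams))
  }

  ## --- normalize -----------------------------------------------------
  .runStage("normalize", p("factors.tsv"), spikes_path, force, {
    sp <- .readTsv(spikes_path)
    cnt <- as.matrix(sp[, design$sample_id, drop = FALSE])
    rownames(cnt) <- sp$spike_id
    fit <- fitSpikeInModel(cnt, sp$labeled == 1, design)
    tab <- sampleFactors(fit)
    tab$theta <- dispersion(fit)
    .writeTsv(tab, p("factors.tsv"))
  })

  ## --- fit -----------------------------------------------------------
  .runStage("fit", p("rates.tsv"), c(counts_path, p("factors.tsv")), force, {
    cm <- .readTsv(counts_path)
    if (!"bond_id" %in% names(cm))
      stop("counts file lacks a bond_id column")
    bad <- !stats::complete.cases(cm[, design$sample_id, drop = FALSE])
    if (any(bad))
      stop("malformed count row(s): ",
           paste(utils::head(cm$bond_id[bad], 3), collapse = ", "))
    counts <- as.matrix(cm[, design$sample_id, drop = FALSE])
    rownames(counts) <- cm$bond_id
    fac_tab <- .readTsv(p("factors.tsv"))
    factors <- list(size_factors = stats::setNames(fac_tab$size_factor,
                                                   fac_tab$sample_id),
                    chi = stats::setNames(fac_tab$chi, fac_tab$sample_id),
                    theta = fac_tab$theta[1])
    fit_cfg <- config$fit %||% list()
    est <- .fitBondModel(counts, design, factors,
                         fit_cfg$model %||% "first_order",
                         min_total_count = fit_cfg$min_total_count %||% 100,
                         n_starts = fit_cfg$n_starts %||% 10, seed = seed)
    .writeTsv(rateTable(est), p("rates.tsv"))
  })

  ## --- yield ---------------------------------------------------------
  if (!is.null(config$yield)) {
    yc <- config$yield
    .runStage("yield", p("yield.tsv"),
              c(yc$junction_rates, yc$site_rates, yc$introns), force, {
      yt <- yieldTable(.readTsv(yc$junction_rates), .readTsv(yc$site_rates),
                       .readTsv(yc$introns), side = yc$side %||% "acceptor")
      .writeTsv(yt, p("yield.tsv"))
    })
  }

  manifest <- list(
    package = "spliceKinetics",
    version = as.character(utils::packageVersion("spliceKinetics")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = seed,
    thresholds = list(min_split_reads = config$min_split_reads %||% 10,
                      min_total_count = (config$fit %||% list())$min_total_count %||% 100,
                      mapq = config$mapq %||% 255),
    input_checksums = as.list(tools::md5sum(
      Filter(file.exists, unique(c(inputs, counts_path, spikes_path))))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
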