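## Seed policy: one global seed; each stochastic module derives its own seed
## by adding the sum of the UTF-8 codes of its name, modulo 2^31 - 1, so a
## single integer reproduces every output byte.
.moduleSeed <- function(seed, module) {
  (as.integer(seed) + sum(utf8ToInt(module))) %% 2147483647L
}

#' Run the full denoise-cluster-tree pipeline
#'
#' Executes encode, decompose, binarize, cluster, consensus, MST and rooting;
#' when the input is a simulation (so ground truth is available) the recovery
#' and clustering metrics are evaluated and embedded in the manifest. With an
#' \code{outdir}, all tabular artifacts are written via [writeOutputs()].
#'
#' @param input a [GenotypeMatrix-class], a [SimulatedGenotypes-class], or a
#'   path to a delimited genotype file (read with [readGenotypeMatrix()]).
#' @param outdir optional output directory.
#' @param rda an [rdaConfig()].
#' @param ae an [autoencoderSpec()]; its seed is overridden by the derived
#'   module seed.
#' @param cluster a [clusterConfig()]; its seed is likewise derived.
#' @param seed single global seed; module seeds are derived from it.
#' @param verbose print per-stage progress.
#' @return a list with elements \code{genotypes}, \code{decomposition},
#'   \code{assignment}, \code{tree}, \code{metrics} (NULL without truth) and
#'   \code{manifest} (config snapshot, files, per-stage timings, convergence
#'   and metric summary, package version).
#' @examples
#' sim <- simulateDataset(simulationConfig(60, 40, 3, fpr = 0, fnr = 0,
#'                                         mr = 0, seed = 1))
#' run <- runPipeline(sim, seed = 1)
#' run$metrics$error   # 0 on clean data
#' @export
runPipeline <- function(input, outdir = NULL, rda = rdaConfig(),
                        ae = autoencoderSpec(), cluster = clusterConfig(),
                        seed = 1L, verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[stage] <<- t1 - t0
    t0 <<- t1
    if (verbose) message(sprintf("[%s] %.2fs", stage, timings[stage]))
  }
  sim <- NULL
  if (is.character(input)) {
    if (!file.exists(input)) stop("input path does not exist: ", input)
    g <- readGenotypeMatrix(input)
  } else if (is(input, "SimulatedGenotypes")) {
    sim <- input
    g <- input@observed
  } else if (is(input, "GenotypeMatrix")) {
    g <- input
  } else stop("unsupported input type: ", class(input)[1L])
  tick("load")

  ae$seed <- .moduleSeed(seed, "extended_rda")
  cluster$seed <- .moduleSeed(seed, "subclone_clustering")
  dec <- rdaDecompose(g, config = rda, spec = ae)
  tick("decompose")

  asg <- clusterSubclones(dec@genotypeCalls, cluster)
  tick("cluster")

  tree <- buildSubcloneTree(dec@genotypeCalls, asg)
  tick("tree")

  metrics <- NULL
  if (!is.null(sim)) {
    metrics <- recoveryReport(dec@genotypeCalls, sim@truth, g)
    metrics <- c(metrics, clusteringScores(asg@labels, sim@trueLabels))
    tick("evaluate")
  }

  run <- list(genotypes = g, decomposition = dec, assignment = asg,
              tree = tree, metrics = metrics)
  files <- character(0)
  if (!is.null(outdir)) {
    files <- writeOutputs(run, outdir)
    tick("write")
  }
  n <- nrow(dec@trace)
  run$manifest <- list(
    config = list(seed = seed, rda = unclass(rda), autoencoder = unclass(ae),
                  cluster = unclass(cluster)),
    files = files,
    timings = as.list(timings),
    convergence = list(iterations = dec@iterationsRun,
                       converged = dec@converged,
                       c1 = dec@trace$c1[n], c2 = dec@trace$c2[n]),
    metrics = metrics,
    n_subclones = asg@nSubclones,
    package_version = as.character(utils::packageVersion("subcloneRDA")))
  run
}

.axisField <- c(sites = "nSites", cells = "nCells", subclones = "nSubclones",
                fpr = "fpr", fnr = "fnr", mr = "mr")

#' Factorial benchmark sweep over one simulation parameter
#'
#' Re-simulates and re-runs the pipeline for every (value, replicate) pair on
#' one axis of the simulation design, holding the other parameters at the
#' base configuration. Replicate seeds are derived deterministically from the
#' base seed. A failing cell is recorded with its error message and the sweep
#' continues.
#'
#' @param base a [simulationConfig()]: the fixed operating point.
#' @param axis one of \code{"sites"}, \code{"cells"}, \code{"subclones"},
#'   \code{"fpr"}, \code{"fnr"}, \code{"mr"}.
#' @param values vector of axis values.
#' @param replicates simulations per value.
#' @param rda,ae,cluster pipeline configurations, as in [runPipeline()].
#' @return long-format data.frame: one row per run with the axis value,
#'   replicate, seed, all recovery and clustering metrics, iteration count
#'   and runtime (seconds); \code{error_message} is NA for successful runs.
#' @export
runBenchmarkSweep <- function(base, axis, values, replicates = 1L,
                              rda = rdaConfig(), ae = autoencoderSpec(),
                              cluster = clusterConfig()) {
  axis <- match.arg(axis, names(.axisField))
  rows <- list()
  for (vi in seq_along(values)) {
    for (rep_ in seq_len(replicates)) {
      cfg <- unclass(base)
      cfg[[.axisField[[axis]]]] <- values[vi]
      runSeed <- (base$seed + 10007L * vi + 101L * rep_) %% 2147483647L
      cfg$seed <- runSeed
      row <- data.frame(axis = axis, value = values[vi], replicate = rep_,
                        seed = runSeed, n_subclones_found = NA_integer_,
                        fpnr_recovered = NA_real_, fpnr_input = NA_real_,
                        fpnr_ratio = NA_real_, missing_accuracy = NA_real_,
                        error = NA_real_, precision = NA_real_,
                        recall = NA_real_, f1 = NA_real_, ari = NA_real_,
                        nmi = NA_real_, v_measure = NA_real_,
                        iterations = NA_integer_, runtime_s = NA_real_,
                        error_message = NA_character_)
      res <- tryCatch({
        sim <- simulateDataset(do.call(simulationConfig, cfg))
        tstart <- proc.time()[["elapsed"]]
        run <- runPipeline(sim, rda = rda, ae = ae, cluster = cluster,
                           seed = runSeed)
        m <- run$metrics
        row$n_subclones_found <- run$assignment@nSubclones
        for (f in c("fpnr_recovered", "fpnr_input", "fpnr_ratio",
                    "missing_accuracy", "error", "precision", "recall", "f1",
                    "ari", "nmi", "v_measure"))
          row[[f]] <- if (is.null(m[[f]]) || is.na(m[[f]])) NA_real_ else m[[f]]
        row$iterations <- run$decomposition@iterationsRun
        row$runtime_s <- proc.time()[["elapsed"]] - tstart
        row
      }, error = function(e) { row$error_message <- conditionMessage(e); row })
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
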