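# Unified front end tying the stages together: one entry point dispatching
# to generate / kih / thread / pore / titrate / report, with YAML or list
# configuration, a machine-readable JSON manifest for every run, and
# deterministic file outputs.

#' Run a pipeline stage
#'
#' Dispatches one analysis stage with a configuration given as an R list
#' or a YAML file path. Every run writes its outputs plus a
#' \code{manifest.json} (inputs, parameters, package version, output
#' hashes) into \code{outDir}. All stages are deterministic given the
#' configuration; stochastic stages (titrate with bootstrap) require an
#' explicit \code{seed} in the configuration. Floating-point values in
#' file outputs are printed at fixed precision so identical configurations
#' yield byte-identical outputs.
#'
#' Subcommands and their configuration entries:
#' \describe{
#'   \item{generate}{\code{type} ("barrel", "two_sheet", "docked"),
#'     \code{n}, \code{heptad}, \code{nHeptads}, optional \code{fills},
#'     \code{r0}, \code{zSlips}, \code{orientations},
#'     \code{registerOffset}.}
#'   \item{kih}{\code{input} (PDB path), optional \code{cutoff} (7.4),
#'     \code{mode} ("centroid"/"atoms"), \code{relaxedHoles}.}
#'   \item{thread}{\code{sequences} (named list), \code{structures}
#'     (named list of PDB paths), \code{cognate} (named list),
#'     optional \code{score}.}
#'   \item{pore}{\code{input}, optional \code{step}, \code{slab},
#'     \code{window}, \code{threshold}, \code{convention}.}
#'   \item{titrate}{\code{input} (CSV with pH, charge_state, count
#'     columns), \code{sites}, optional \code{hill}, \code{bootstrap},
#'     \code{seed}.}
#'   \item{report}{\code{inputs} (vector of PDB paths): one combined CSV
#'     row per structure with oligomer state, interface type, symmetry
#'     and pore summary.}
#' }
#'
#' @param subcommand one of \code{"generate"}, \code{"kih"},
#'   \code{"thread"}, \code{"pore"}, \code{"titrate"}, \code{"report"}
#' @param config list of parameters, or path to a YAML file
#' @param outDir output directory (created if needed)
#' @return (invisibly) list of written file paths
#' @export
runPipeline <- function(subcommand = c("generate", "kih", "thread", "pore",
                                       "titrate", "report"),
                        config = list(), outDir = ".") {
  subcommand <- match.arg(subcommand)
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  files <- switch(subcommand,
                  generate = .stageGenerate(config, outDir),
                  kih = .stageKih(config, outDir),
                  thread = .stageThread(config, outDir),
                  pore = .stagePore(config, outDir),
                  titrate = .stageTitrate(config, outDir),
                  report = .stageReport(config, outDir))
  manifest <- list(
    subcommand = subcommand,
    parameters = config,
    package = as.character(utils::packageVersion("ccbarrel")),
    outputs = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  mf <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, manifest = mf))
}

.cfg <- function(config, name, default = NULL, required = FALSE) {
  if (!is.null(config[[name]])) return(config[[name]])
  if (required) stop("configuration entry '", name, "' is required")
  default
}

.fmtNum <- function(x, digits = 6) {
  ifelse(is.na(x), NA, formatC(x, digits = digits, format = "g"))
}

.stageGenerate <- function(config, outDir) {
  type <- .cfg(config, "type", "barrel")
  n <- .cfg(config, "n", required = TRUE)
  heptad <- .cfg(config, "heptad", required = TRUE)
  nHeptads <- .cfg(config, "nHeptads", 4)
  seqStr <- buildSequence(heptad, nHeptads,
                          fills = unlist(.cfg(config, "fills")))
  params <- crickParams(n, r0 = .cfg(config, "r0"),
                        zSlips = .cfg(config, "zSlips", 0),
                        orientations = .cfg(config, "orientations", 1L))
  model <- if (type == "barrel") {
    buildBarrel(params, seqStr,
                registerOffset = .cfg(config, "registerOffset", 0))
  } else {
    buildCollapsed(params, seqStr, arrangement = type)
  }
  out <- file.path(outDir, .cfg(config, "output", "model.pdb"))
  writeStructure(model, out)
  out
}

.stageKih <- function(config, outDir) {
  model <- readStructure(.cfg(config, "input", required = TRUE))
  res <- analyzeKih(model,
                    cutoff = .cfg(config, "cutoff", 7.4),
                    mode = .cfg(config, "mode", "centroid"),
                    relaxedHoles = isTRUE(.cfg(config, "relaxedHoles", FALSE)))
  knobsCsv <- file.path(outDir, "knobs.csv")
  kn <- res$knobs
  for (col in c("d1", "d2", "d3", "d4", "packingAngle"))
    kn[[col]] <- as.numeric(.fmtNum(kn[[col]]))
  utils::write.csv(kn, knobsCsv, row.names = FALSE)
  sym <- res$symmetry
  rep <- list(
    source = model@source,
    nHelices = length(res$helices),
    nKnobs = nrow(res$knobs),
    knobRegisters = res$knobRegisters,
    interfaceType = res$interfaceType,
    orientationPattern = res$orientationPattern,
    assemblies = res$assemblies,
    symmetry = if (is.null(sym)) NULL else list(
      label = sym@label, rotationOrder = sym@rotationOrder,
      meanRotation = as.numeric(.fmtNum(sym@meanRotation)),
      meanScrew = as.numeric(.fmtNum(sym@meanScrew))))
  repJson <- file.path(outDir, "kih_report.json")
  jsonlite::write_json(rep, repJson, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  c(knobsCsv, repJson)
}

.stageThread <- function(config, outDir) {
  seqs <- unlist(.cfg(config, "sequences", required = TRUE))
  paths <- .cfg(config, "structures", required = TRUE)
  structures <- lapply(paths, readStructure)
  names(structures) <- names(paths)
  cognate <- unlist(.cfg(config, "cognate", required = TRUE))
  sm <- specificityMatrix(seqs, structures, cognate,
                          score = .cfg(config, "score", "steric"))
  matCsv <- file.path(outDir, "specificity_matrix.csv")
  vals <- apply(sm@values, c(1, 2), function(v) as.numeric(.fmtNum(v)))
  utils::write.csv(vals, matCsv)
  detJson <- file.path(outDir, "specificity_details.json")
  jsonlite::write_json(list(score = sm@score, cognate = as.list(sm@cognate),
                            raw = apply(sm@raw, c(1, 2), function(v)
                              as.numeric(.fmtNum(v))),
                            sd = apply(sm@sd, c(1, 2), function(v)
                              as.numeric(.fmtNum(v)))),
                       detJson, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  c(matCsv, detJson)
}

.stagePore <- function(config, outDir) {
  model <- readStructure(.cfg(config, "input", required = TRUE))
  helices <- detectHelices(model)
  axis <- barrelAxis(model, helices)
  prof <- poreProfile(model, axis,
                      step = .cfg(config, "step", 0.5),
                      slab = .cfg(config, "slab", 1.0),
                      convention = .cfg(config, "convention", "vdw"))
  summ <- poreSummary(prof,
                      centralWindow = .cfg(config, "window", 0.7),
                      openThreshold = .cfg(config, "threshold", 0.5))
  profCsv <- file.path(outDir, "pore_profile.csv")
  utils::write.csv(data.frame(z = as.numeric(.fmtNum(prof@stations)),
                              radius = as.numeric(.fmtNum(prof@radius))),
                   profCsv, row.names = FALSE)
  summJson <- file.path(outDir, "pore_summary.json")
  jsonlite::write_json(lapply(summ, function(v)
    if (is.numeric(v)) as.numeric(.fmtNum(v)) else v),
    summJson, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  c(profCsv, summJson)
}

.stageTitrate <- function(config, outDir) {
  input <- .cfg(config, "input", required = TRUE)
  sites <- .cfg(config, "sites", required = TRUE)
  tab <- utils::read.csv(input)
  need <- c("pH", "charge_state", "count")
  if (!all(need %in% names(tab)))
    stop("titration input needs columns: ", paste(need, collapse = ", "))
  pH <- sort(unique(tab$pH))
  counts <- matrix(0L, length(pH), sites + 1)
  for (r in seq_len(nrow(tab))) {
    i <- match(tab$pH[r], pH)
    j <- tab$charge_state[r] + 1
    counts[i, j] <- counts[i, j] + tab$count[r]
  }
  series <- new("ChargeStateSeries", pH = pH, counts = counts)
  fit <- fitMacroscopicPkas(series, x = sites,
                            hill = .cfg(config, "hill", 1),
                            nBoot = .cfg(config, "bootstrap", 200),
                            seed = .cfg(config, "seed", required = TRUE))
  fitJson <- file.path(outDir, "titration_fit.json")
  jsonlite::write_json(list(
    pka = as.numeric(.fmtNum(fit@pka)),
    hill = fit@hill,
    ci = if (nrow(fit@ci) == 2) apply(fit@ci, c(1, 2), function(v)
      as.numeric(.fmtNum(v))) else NULL,
    rss = as.numeric(.fmtNum(fit@rss)),
    converged = fit@converged, identifiable = fit@identifiable),
    fitJson, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  grid <- seq(min(pH), max(pH), by = 0.1)
  curves <- transitionCurves(polyproticModel(fit@pka, fit@hill), grid)
  curvesCsv <- file.path(outDir, "titration_curves.csv")
  df <- data.frame(pH = grid, t(apply(curves, c(1, 2), function(v)
    as.numeric(.fmtNum(v)))))
  names(df) <- c("pH", paste0("f", seq_len(sites)))
  utils::write.csv(df, curvesCsv, row.names = FALSE)
  c(fitJson, curvesCsv)
}

.stageReport <- function(config, outDir) {
  inputs <- .cfg(config, "inputs", required = TRUE)
  rows <- lapply(inputs, function(p) {
    model <- readStructure(p)
    res <- analyzeKih(model)
    sym <- res$symmetry
    symLabel <- if (is.null(sym)) "NA" else {
      lab <- sym@label
      if (lab %in% c("Cn", "Dn") && !is.na(sym@rotationOrder))
        lab <- sub("n", sym@rotationOrder, lab)
      lab
    }
    pore <- tryCatch({
      ps <- poreSummary(poreProfile(model, barrelAxis(model, res$helices)))
      c(minD = ps$minDiameter, maxD = ps$maxDiameter,
        open = as.numeric(ps$open))
    }, error = function(e) c(minD = NA, maxD = NA, open = NA))
    data.frame(input = basename(p), nHelices = length(res$helices),
               interfaceType = res$interfaceType,
               orientation = res$orientationPattern,
               symmetry = symLabel,
               minDiameter = as.numeric(.fmtNum(pore[["minD"]])),
               maxDiameter = as.numeric(.fmtNum(pore[["maxD"]])),
               open = pore[["open"]],
               structureClass = ifelse(isTRUE(pore[["open"]] > 0),
                                       "barrel", "collapsed"),
               stringsAsFactors = FALSE)
  })
  out <- file.path(outDir, "assembly_report.csv")
  utils::write.csv(do.call(rbind, rows), out, row.names = FALSE)
  out
}
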