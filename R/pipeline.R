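#' Configuration of a full pipeline run
#'
#' Validates paths and bundles the stage settings. Either an existing
#' image/outline pair is analysed, or a synthetic cohort is simulated
#' (\code{simulate = list(nPerGroup, effectModel or measure/structures)}).
#'
#' @param outputDir directory for all outputs (created if missing).
#' @param imagePath optional NIfTI stack to analyse.
#' @param outlinePath outlines file for \code{imagePath} (required with
#'   it).
#' @param simulate optional list describing a synthetic cohort run:
#'   nPerGroup (named), structures, nSlices, render.
#' @param geometry an \linkS4class{AcquisitionGeometry}.
#' @param n3 list from \code{\link{n3Params}}.
#' @param seed top-level seed; every stochastic stage derives its seed
#'   from it.
#' @param sliceRange optional integer vector of slices to analyse.
#' @param alpha significance level of the statistical battery.
#' @return Validated config (class "RunConfig").
#' @export
runConfig <- function(outputDir, imagePath = NULL, outlinePath = NULL,
                      simulate = NULL, geometry = acquisitionGeometry(),
                      n3 = n3Params(), seed = 1L, sliceRange = NULL,
                      alpha = 0.05) {
  if (is.null(simulate) && is.null(imagePath))
    stop("validation error: field 'imagePath' or 'simulate' must be given")
  if (!is.null(imagePath)) {
    if (!file.exists(imagePath))
      stop("validation error: field 'imagePath': no such file: ", imagePath)
    if (is.null(outlinePath))
      stop("validation error: field 'outlinePath' is required with imagePath")
    if (!file.exists(outlinePath))
      stop("validation error: field 'outlinePath': no such file: ",
           outlinePath)
  }
  structure(list(outputDir = outputDir, imagePath = imagePath,
                 outlinePath = outlinePath, simulate = simulate,
                 geometry = geometry, n3 = n3, seed = as.integer(seed),
                 sliceRange = sliceRange, alpha = alpha),
            class = "RunConfig")
}

#' Run the full pipeline
#'
#' Executes simulate-or-load, bias correction, threshold segmentation,
#' CSA/volume computation and, for cohort runs, the statistical battery;
#' writes all tables and a reproducibility manifest (seeds, parameter
#' echo and per-file checksums) to the output directory. Stage failures
#' abort with the failing stage named.
#'
#' @param config a \code{\link{runConfig}}.
#' @return The manifest, invisibly (also written as manifest.json).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  written <- character()

  subjects <- stage("simulate-or-load", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      structures <- if (!is.null(sim$structures)) sim$structures
                    else thighMuscles()
      em <- if (!is.null(sim$effectModel)) sim$effectModel
            else defaultEffectModel(structures = structures)
      design <- cohortDesign(sim$nPerGroup, em, seed = config$seed)
      nS <- if (!is.null(sim$nSlices)) sim$nSlices else 8L
      template <- if (isTRUE(sim$render)) {
        mus <- intersect(thighMuscles(), unique(em$structure))
        if (!length(mus)) mus <- thighMuscles()
        defaultPhantomSpec(nSlices = nS, muscles = mus,
                           geometry = config$geometry, seed = config$seed)
      }
      co <- generateCohort(design, template, render = isTRUE(sim$render))
      if (isTRUE(sim$render)) {
        lapply(co$phantoms, function(p)
          list(id = paste(p$subject, p$session, sep = "_"),
               subject = p$subject, group = p$group, session = p$session,
               stack = p$stack, outlines = p$outlines))
      } else {
        attr(co$volumes, "volumesOnly") <- TRUE
        co$volumes
      }
    } else {
      stack <- readImageStack(config$imagePath,
                              config$geometry@sliceThicknessMm,
                              config$geometry@intersliceGapMm)
      outl <- readOutlines(config$outlinePath)
      list(list(id = "subject", subject = "subject", group = "",
                session = "", stack = stack, outlines = outl))
    }
  })

  if (is.data.frame(subjects)) {
    volumes <- subjects                      # simulated volumes-only run
  } else {
    volRows <- list()
    for (su in subjects) {
      corrected <- stage("correct", correctStack(su$stack, config$n3))
      seg <- stage("segment",
                   classifyStack(corrected$corrected, su$outlines,
                                 seed = config$seed))
      vt <- stage("volumes", {
        csa <- labelCSATable(seg$labels, subject = su$subject,
                             session = su$session)
        volumeTableFromCSA(csa, su$stack@geometry,
                           slices = config$sliceRange)
      })
      vt$group <- su$group
      f <- file.path(config$outputDir,
                     paste0("thresholds_", su$id, ".csv"))
      writeVolumeTable(seg$thresholds, f); written <- c(written, f)
      volRows[[su$id]] <- vt
    }
    vtab <- do.call(rbind, c(volRows, make.row.names = FALSE))
    volumes <- data.frame(subject = vtab$subject, group = vtab$group,
                          session = vtab$session,
                          structure = vtab$structure,
                          volume = vtab$tissueVolume,
                          intramatVolume = vtab$intramatVolume)
  }
  f <- file.path(config$outputDir, "volumes.csv")
  writeVolumeTable(volumes, f); written <- c(written, f)

  haveSessions <- all(c("before", "after") %in% volumes$session) &&
    length(unique(volumes$group[volumes$group != ""])) >= 2L
  if (haveSessions) {
    st <- stage("stats", cohortStats(
      volumes[c("subject", "group", "session", "structure", "volume")],
      alpha = config$alpha))
    for (nm in names(st)) {
      f <- file.path(config$outputDir, paste0("stats_", nm, ".csv"))
      writeVolumeTable(st[[nm]], f); written <- c(written, f)
    }
  }

  manifest <- list(
    package = "thighMAT",
    version = as.character(utils::packageVersion("thighMAT")),
    seed = config$seed,
    alpha = config$alpha,
    n3 = config$n3,
    geometry = list(fovMm = config$geometry@fovMm,
                    matrixPx = config$geometry@matrixPx,
                    sliceSpacingMm = config$geometry@sliceSpacingMm),
    simulate = if (!is.null(config$simulate))
      config$simulate[intersect(names(config$simulate),
                                c("nPerGroup", "structures", "nSlices",
                                  "render"))],
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = lapply(stats::setNames(written, basename(written)),
                   function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest,
                       file.path(config$outputDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
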