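#' Generate a synthetic longitudinal cohort
#'
#' Draws, for every subject of every group, a true baseline volume and a
#' true before-to-after change per structure from the design's effect
#' model (both Normal; baselines are redrawn until positive). The drawn
#' values are the cohort's ground truth and are returned as a long
#' volume table. With \code{render = TRUE} a phantom image stack is
#' additionally rendered per subject and session from \code{template}:
#' each muscle polygon is scaled so that its rendered volume, relative
#' to the template, equals the subject's drawn volume relative to the
#' group baseline mean (exact up to pixel quantization), which keeps
#' study-scale effect models compatible with any template anatomy.
#'
#' A fixed seed gives bit-identical output.
#'
#' @param design a \linkS4class{CohortDesign}.
#' @param template a \linkS4class{PhantomSpec} used for rendering
#'   (required when \code{render = TRUE}).
#' @param render render phantom image stacks per subject/session
#'   (default FALSE: the drawn true volumes alone are returned, which is
#'   what the statistical battery consumes).
#' @return List with \code{volumes}
#'   (data.frame(subject, group, session, structure, volume)) and, when
#'   rendering, \code{phantoms}: a list of lists(subject, group, session,
#'   stack, truth, outlines).
#' @export
#' @examples
#' em <- data.frame(structure = "QF", group = c("TR", "CTR"),
#'                  baselineMean = c(1993.9, 2111.6), baselineSd = 0,
#'                  changeMean = c(0, -342.2), changeSd = 0)
#' co <- generateCohort(cohortDesign(c(TR = 3, CTR = 3), em, seed = 7))
#' subset(co$volumes, structure == "QF" & group == "CTR")
generateCohort <- function(design, template = NULL, render = FALSE) {
  validObject(design)
  if (render && is.null(template))
    stop("design error: rendering requires a template PhantomSpec")
  em <- design@effectModel
  groups <- names(design@nPerGroup)
  if (!all(unique(em$group) %in% groups))
    stop("design error: effect-model groups not in nPerGroup")
  rows <- list()
  phantoms <- list()
  withSeed(design@seed, {
    for (g in groups) {
      emg <- em[em$group == g, , drop = FALSE]
      if (!nrow(emg))
        stop("design error: no effect-model rows for group ", g)
      for (i in seq_len(design@nPerGroup[[g]])) {
        subj <- sprintf("%s%02d", g, i)
        for (k in seq_len(nrow(emg))) {
          base <- stats::rnorm(1, emg$baselineMean[k], emg$baselineSd[k])
          tries <- 0L
          while (base <= 0 && tries < 100L) {
            base <- stats::rnorm(1, emg$baselineMean[k], emg$baselineSd[k])
            tries <- tries + 1L
          }
          if (base <= 0) stop("design error: baseline distribution ",
                              "produces non-positive volumes")
          chg <- stats::rnorm(1, emg$changeMean[k], emg$changeSd[k])
          rows[[length(rows) + 1L]] <- data.frame(
            subject = subj, group = g,
            session = c("before", "after"),
            structure = emg$structure[k],
            volume = c(base, base + chg))
        }
      }
    }
  })
  volumes <- do.call(rbind, rows)
  rownames(volumes) <- NULL
  out <- list(volumes = volumes, design = design)
  if (render) {
    out$phantoms <- renderCohortPhantoms(volumes, template, em)
  }
  out
}

## Render one phantom per subject/session.  Each subject's drawn volume is
## realized RELATIVE to the group baseline mean of its structure: a drawn
## volume of 0.9 x baselineMean renders the template muscle scaled to 90%
## of its template volume.  This keeps study-scale effect models (volumes
## in the thousands of cm^3) compatible with any template anatomy; the
## polygon linear factor is the square root of the volume ratio since the
## slice count is fixed.
renderCohortPhantoms <- function(volumes, template, effectModel) {
  ph0 <- generatePhantom(template)
  base <- ph0$truth@volumes
  baseVol <- function(st) {
    v <- base$tissueVolume[base$structure == st]
    if (!length(v)) NA_real_ else v
  }
  refVol <- function(st, g) {
    v <- effectModel$baselineMean[effectModel$structure == st &
                                    effectModel$group == g]
    if (!length(v)) NA_real_ else v[1]
  }
  groupsDef <- muscleGroups()
  phantoms <- list()
  keys <- unique(volumes[c("subject", "group", "session")])
  for (r in seq_len(nrow(keys))) {
    subj <- keys$subject[r]; ses <- keys$session[r]; grp <- keys$group[r]
    vv <- volumes[volumes$subject == subj & volumes$session == ses, ]
    spec <- template
    ## relative targets per muscle: direct rows, aggregate rows applied
    ## uniformly to their member muscles
    rel <- list()
    for (k in seq_len(nrow(vv))) {
      st <- vv$structure[k]
      rt <- vv$volume[k] / refVol(st, grp)
      if (!is.finite(rt) || rt <= 0) next
      if (st %in% names(spec@muscles)) {
        rel[[st]] <- rt
      } else if (st %in% names(groupsDef)) {
        for (m in intersect(groupsDef[[st]], names(spec@muscles)))
          rel[[m]] <- rt
      }
    }
    for (m in names(rel))
      spec@muscles[[m]] <- scalePolygon(spec@muscles[[m]], sqrt(rel[[m]]))
    if ("SAT" %in% vv$structure) {
      rt <- vv$volume[vv$structure == "SAT"] / refVol("SAT", grp)
      if (is.finite(rt) && rt > 0) {
        ax <- spec@fascia$semiAxes
        ringPx0 <- pi * (prod(spec@skin$semiAxes) - prod(ax))
        s <- sqrt(1 + rt * ringPx0 / (pi * prod(ax)))
        spec@skin$semiAxes <- ax * s
      }
    }
    spec@seed <- (template@seed + 7717L * r) %% .Machine$integer.max
    ph <- generatePhantom(spec)
    phantoms[[length(phantoms) + 1L]] <-
      list(subject = subj, group = grp, session = ses,
           stack = ph$stack, truth = ph$truth, outlines = ph$outlines)
  }
  phantoms
}
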