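## Study pipeline: per-hemisphere dimension tables, hemisphere contrasts,
## dimension-versus-physiology correlations, Fisher-z sample sizes, and the
## DLA matrix-size experiment.

#' Maximum slope of a contrast transit curve
#'
#' The peak of the differentiated intensity-time curve, computed with
#' central differences (one-sided differences at the ends). Used as the
#' hemodynamic covariate: a faster bolus upslope reflects more vessels
#' feeding the malformation.
#'
#' @param curve an [IntensityTimeCurve-class] (uniform sampling enforced by
#'   the class).
#' @return the maximum derivative, in intensity units per second.
#' @examples
#' maxSlope(intensityTimeCurve(0:10, 2 + 5 * (0:10)))  # 5
#' @rdname maxSlope
#' @export
setMethod("maxSlope", "IntensityTimeCurve", function(curve) {
  t <- curve@times; I <- curve@intensities
  n <- length(t)
  d <- numeric(n)
  d[1L] <- (I[2L] - I[1L]) / (t[2L] - t[1L])
  d[n] <- (I[n] - I[n - 1L]) / (t[n] - t[n - 1L])
  if (n > 2L)
    d[2:(n - 1L)] <- (I[3:n] - I[1:(n - 2L)]) / (t[3:n] - t[1:(n - 2L)])
  max(d)
})

#' Mean nidus diameter from four angiographic measurements
#'
#' The nidus size covariate: the arithmetic mean of the minimum and maximum
#' diameters measured in the coronal and sagittal views (four values).
#'
#' @param diameters numeric vector of the four diameters in cm, or the
#'   first of four separate positive values.
#' @param ... the remaining diameters when given separately.
#' @return mean diameter in cm.
#' @examples
#' nidusMeanDiameter(2.0, 3.0, 2.5, 4.1)  # 2.9
#' @export
nidusMeanDiameter <- function(diameters, ...) {
  d <- c(diameters, ...)
  if (length(d) != 4L) stop("exactly four diameters are required")
  if (any(!is.finite(d)) || any(d <= 0))
    stop("diameters must be positive")
  mean(d)
}

#' Correlate fractal dimension with a covariate
#'
#' Pearson correlation with the two-sided p-value from the t transform of
#' r, plus the OLS regression line of the covariate on the dimension.
#'
#' @param fd numeric vector of dimension values.
#' @param covariate numeric vector, same length (>= 3 pairs).
#' @return a list with `r`, `p`, `n`, `slope`, `intercept`.
#' @examples
#' correlateFD(1:10, 2 * (1:10) + 3)  # r = 1
#' @export
correlateFD <- function(fd, covariate) {
  ok <- is.finite(fd) & is.finite(covariate)
  fd <- fd[ok]; covariate <- covariate[ok]
  n <- length(fd)
  if (n < 3L) stop("need at least 3 paired finite values")
  if (sd(fd) == 0 || sd(covariate) == 0)
    stop("zero variance: correlation undefined")
  ct <- cor.test(fd, covariate, method = "pearson")
  fit <- lm(covariate ~ fd)
  list(r = unname(ct$estimate), p = ct$p.value, n = n,
       slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]))
}

#' Sample size for detecting a correlation (Fisher-z method)
#'
#' n = ceiling(((z_{1-alpha/2} + z_{power}) / atanh(r))^2 + 3), the
#' standard Fisher-z sample-size formula for a two-sided test of a Pearson
#' correlation.
#'
#' @param r expected correlation, 0 < |r| < 1.
#' @param alpha two-sided significance level.
#' @param power target power.
#' @return required number of subjects (integer).
#' @examples
#' sampleSizeFromR(0.913)  # 7
#' @export
sampleSizeFromR <- function(r, alpha = 0.05, power = 0.80) {
  if (!is.finite(r) || abs(r) >= 1 || r == 0)
    stop("r must satisfy 0 < |r| < 1")
  z <- qnorm(1 - alpha / 2) + qnorm(power)
  as.integer(ceiling((z / atanh(abs(r)))^2 + 3))
}

.methodNames <- c("Db", "Dm", "D0", "D1", "D2")

#' All five dimension estimates of one binary image
#'
#' @param image a nonempty [BinaryImage-class].
#' @param rThreshold correlation threshold for range selection.
#' @param nMax largest Minkowski structuring-element index.
#' @return named numeric: Db, Dm, D0, D1, D2.
#' @export
allDimensions <- function(image, rThreshold = 0.995, nMax = NULL) {
  db <- fdValue(boxDimension(image, rThreshold = rThreshold))
  dm <- fdValue(minkowskiDimension(image, nMax = nMax,
                                   rThreshold = rThreshold))
  sp <- generalizedSpectrum(image, q = c(0, 1, 2), rThreshold = rThreshold)
  c(Db = db, Dm = dm, D0 = dqValues(sp)[1L], D1 = dqValues(sp)[2L],
    D2 = dqValues(sp)[3L])
}

.sem <- function(x) if (length(x) < 2L) 0 else sd(x) / sqrt(length(x))

#' Hemisphere contrasts from a long-format dimension table
#'
#' Summarizes a per-subject, per-region dimension table the way the study
#' reports it: group means with SEM for the patients' AVM and non-AVM
#' hemispheres, the controls' left and right hemispheres and the whole
#' images, plus paired contrasts (AVM vs non-AVM within patients, left vs
#' right within controls) with paired t statistics.
#'
#' @param fdTable data.frame with columns subject, group ("patient" /
#'   "control"), region ("AVM", "noAVM", "left", "right", "total"), method,
#'   value. At least 2 subjects per group are required, and every subject
#'   must carry both hemisphere regions.
#' @return a list with `summary` (region x method means and SEM) and
#'   `paired` (per-method paired mean differences, t and p).
#' @export
compareHemispheres <- function(fdTable) {
  need <- c("subject", "group", "region", "method", "value")
  if (!all(need %in% names(fdTable)))
    stop("fdTable must have columns ", paste(need, collapse = ", "))
  summary <- do.call(rbind, lapply(
    split(fdTable, list(fdTable$group, fdTable$region, fdTable$method),
          drop = TRUE),
    function(d) data.frame(group = d$group[1L], region = d$region[1L],
                           method = d$method[1L], mean = mean(d$value),
                           sem = .sem(d$value), n = nrow(d))))
  rownames(summary) <- NULL
  summary <- summary[order(summary$group, summary$region, summary$method), ]

  pairedOne <- function(d, a, b, label) {
    da <- d[d$region == a, ]; db <- d[d$region == b, ]
    if (nrow(da) < 2L || nrow(db) < 2L) return(NULL)
    db <- db[match(da$subject, db$subject), ]
    if (any(is.na(db$value))) stop("missing hemisphere for some subject")
    diff <- da$value - db$value
    if (sd(diff) == 0) {
      tt <- list(statistic = c(t = if (mean(diff) == 0) 0 else Inf),
                 p.value = if (mean(diff) == 0) 1 else 0)
    } else {
      tt <- t.test(da$value, db$value, paired = TRUE)
    }
    data.frame(contrast = label, method = d$method[1L],
               meanDiff = mean(diff), semDiff = .sem(diff),
               t = unname(tt$statistic), p = tt$p.value, n = nrow(da))
  }
  paired <- do.call(rbind, unlist(lapply(
    split(fdTable, fdTable$method), function(d) {
      list(pairedOne(d[d$group == "patient", ], "AVM", "noAVM",
                     "patient AVM - noAVM"),
           pairedOne(d[d$group == "control", ], "left", "right",
                     "control left - right"))
    }), recursive = FALSE))
  rownames(paired) <- NULL
  list(summary = summary, paired = paired)
}

#' DLA matrix-size sensitivity experiment
#'
#' Replicates the simulation used to probe how the image matrix size
#' biases the estimators: grows `replicates` DLA clusters, rasterizes each
#' on a power-of-two 512 x 512 grid and on the in-vivo 364 x 436 geometry
#' (grown at 436 x 436, centre-cropped), and evaluates the box-counting
#' and Minkowski dimensions of every whole image and of its left and right
#' halves.
#'
#' @param replicates number of clusters per geometry.
#' @param seed base RNG seed; cluster i uses seed `seed * 1000 + i`.
#' @param rThreshold correlation threshold for range selection.
#' @param nMax largest Minkowski structuring-element index.
#' @return data.frame with columns geometry, replicate, region
#'   (whole/left/right), Db, Dm.
#' @export
dlaMatrixSizeExperiment <- function(replicates = 10L, seed = 1L,
                                    rThreshold = 0.995, nMax = NULL) {
  rows <- list()
  for (i in seq_len(replicates)) {
    s <- as.integer(seed) * 1000L + i
    for (geom in c("512x512", "364x436")) {
      img <- if (geom == "512x512") generateDLA(512L, 512L, seed = s)
             else generateDLA364x436(seed = s)
      halves <- splitHemispheres(img)
      for (reg in c("whole", "left", "right")) {
        im <- switch(reg, whole = img, left = halves$left,
                     right = halves$right)
        rows[[length(rows) + 1L]] <- data.frame(
          geometry = geom, replicate = i, region = reg,
          Db = fdValue(boxDimension(im, rThreshold = rThreshold)),
          Dm = fdValue(minkowskiDimension(im, nMax = nMax,
                                          rThreshold = rThreshold)))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}


## Study regression protocol. Within a cohort the same scaling window is
## used for every subject (the constant-number-of-points convention), so
## subject-to-subject differences reflect the images, not window jumps:
## - box counting and the generalized spectrum use the dyadic series with
##   the single-pixel scale dropped (epsilon = 2 .. 2^kmax); at epsilon = 1
##   every occupied box holds exactly one pixel, so that point carries no
##   mass information and only biases the fit;
## - the Minkowski fit uses the R-threshold range selected once on the
##   pooled cohort curve (elementwise mean of log areas).
.fixedDyadicRange <- function(n) {
  new("RegressionRange", first = if (n >= 4L) 2L else 1L,
      last = as.integer(n), flagged = FALSE)
}

.pooledCurveRange <- function(curves, rThreshold) {
  lm_ <- rowMeans(vapply(curves, function(cv) log(cv@measures),
                         numeric(length(curves[[1]]@measures))))
  selectLinearRange(scalingCurve(curves[[1]]@scales, exp(lm_),
                                 curves[[1]]@method), rThreshold)
}

## all five dimensions for a list of equally sized images, shared windows
.studyDims <- function(images, rThreshold, nMax) {
  boxCurves <- lapply(images, boxCounts)
  minkCurves <- lapply(images, minkowskiAreas, nMax = nMax)
  moms <- lapply(images, partitionMoments, q = c(0, 1, 2))
  boxRange <- .fixedDyadicRange(length(boxCurves[[1L]]@scales))
  minkRange <- .pooledCurveRange(minkCurves, rThreshold)
  out <- t(mapply(function(bc, mc, pm) {
    sp <- .spectrumFromMoments(pm@boxSizes, pm@extent, pm@moments,
                               pm@entropy, c(0, 1, 2), boxRange)
    c(Db = fdValue(fitDimension(bc, boxRange)),
      Dm = fdValue(fitDimension(mc, minkRange)),
      D0 = sp@Dq[1L], D1 = sp@Dq[2L], D2 = sp@Dq[3L])
  }, boxCurves, minkCurves, moms))
  rownames(out) <- names(images)
  out
}

.asConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(nPatients = 10L, nControls = 10L, seed = 1L,
                   rThreshold = 0.995, nMax = NULL,
                   complexity = list(dMin = 40L, dMax = 160L),
                   noise = list(slopeSD = 0.1, diamSD = 0.05),
                   outputDir = NULL, dlaSensitivity = FALSE,
                   dlaReplicates = 10L)
  defaults[names(config)] <- config
  defaults
}

#' Run the full synthetic study
#'
#' End-to-end orchestration on a synthetic cohort: generates the cohort,
#' computes all five dimensions (Db, Dm, D0, D1, D2) for every hemisphere
#' and for the recombined whole image, summarizes hemisphere contrasts,
#' correlates the AVM-side dimensions with the peak contrast-transit slope
#' and with the mean nidus diameter, converts those correlations into
#' Fisher-z sample sizes, and (optionally) appends the DLA matrix-size
#' experiment. Fully reproducible: the report is a pure function of the
#' configuration, and rerunning with the same config writes byte-identical
#' CSVs.
#'
#' Within the cohort every subject is fitted over the same scaling window
#' (the constant-number-of-points convention), so between-subject
#' differences reflect the images rather than window jumps: box counting
#' and the generalized spectrum use the dyadic box sizes with the
#' single-pixel scale dropped, and the Minkowski regression range is
#' selected once, by the usual correlation threshold, on the pooled cohort
#' curve. Whole-image and hemisphere tables use their own shared windows.
#'
#' @param config a list (or path to a YAML file) with any of: `nPatients`,
#'   `nControls`, `seed`, `rThreshold`, `nMax`, `complexity`, `noise`
#'   (passed to [generateCohort()]), `outputDir` (write `report.csv`,
#'   `correlations.csv` and `summary.txt` there when non-NULL),
#'   `dlaSensitivity` (logical) and `dlaReplicates`.
#' @return a [CohortReport-class].
#' @examples
#' \donttest{
#' rep <- runStudy(list(nPatients = 3, nControls = 3, seed = 1))
#' rep
#' }
#' @export
runStudy <- function(config = list()) {
  cfg <- .asConfig(config)
  cohort <- generateCohort(nPatients = cfg$nPatients,
                           nControls = cfg$nControls, seed = cfg$seed,
                           complexity = cfg$complexity, noise = cfg$noise)
  hemiImages <- list(); hemiMeta <- list()
  wholeImages <- list(); wholeMeta <- list()
  subjRows <- list()
  for (s in cohort) {
    whole <- BinaryImage(cbind(pixels(s@left), pixels(s@right)))
    regions <- if (s@group == "patient") {
      stats::setNames(c("AVM", "noAVM"),
                      c(s@avmSide, setdiff(c("left", "right"), s@avmSide)))
    } else {
      c(left = "left", right = "right")
    }
    for (side in names(regions)) {
      hemiImages[[length(hemiImages) + 1L]] <- slot(s, side)
      hemiMeta[[length(hemiMeta) + 1L]] <- data.frame(
        subject = s@id, group = s@group, hemisphere = side,
        region = regions[[side]])
    }
    wholeImages[[length(wholeImages) + 1L]] <- whole
    wholeMeta[[length(wholeMeta) + 1L]] <- data.frame(
      subject = s@id, group = s@group, hemisphere = "both",
      region = "total")
    subjRows[[length(subjRows) + 1L]] <- data.frame(
      subject = s@id, group = s@group, avmSide = s@avmSide,
      branchesLeft = s@branchCounts[["left"]],
      branchesRight = s@branchCounts[["right"]],
      maxSlope = maxSlope(s@curve),
      nidusDiameter = if (s@group == "patient")
        nidusMeanDiameter(s@nidusDiameters) else NA_real_)
  }
  hemiDims <- .studyDims(hemiImages, cfg$rThreshold, cfg$nMax)
  wholeDims <- .studyDims(wholeImages, cfg$rThreshold, cfg$nMax)
  long <- function(meta, dims) {
    do.call(rbind, lapply(seq_along(meta), function(i)
      cbind(meta[[i]][rep(1L, 5L), ], method = colnames(dims),
            value = dims[i, ], row.names = NULL)))
  }
  fdTable <- rbind(long(hemiMeta, hemiDims), long(wholeMeta, wholeDims))
  rownames(fdTable) <- NULL
  subjects <- do.call(rbind, subjRows); rownames(subjects) <- NULL

  contrasts <- compareHemispheres(fdTable)

  ## correlations use the AVM-side hemisphere values of the patients
  avm <- fdTable[fdTable$region == "AVM", ]
  corRows <- list(); ssRows <- list()
  nPat <- sum(subjects$group == "patient")
  for (m in if (nPat >= 3L) .methodNames else character(0)) {
    fd <- avm$value[avm$method == m]
    ord <- match(avm$subject[avm$method == m], subjects$subject)
    for (cov in c("maxSlope", "nidusDiameter")) {
      cv <- subjects[[cov]][ord]
      cr <- correlateFD(fd, cv)
      corRows[[length(corRows) + 1L]] <- data.frame(
        method = m, covariate = cov, r = cr$r, p = cr$p, n = cr$n,
        slope = cr$slope, intercept = cr$intercept)
      ssRows[[length(ssRows) + 1L]] <- data.frame(
        method = m, covariate = cov,
        n = sampleSizeFromR(cr$r))
    }
  }
  correlations <- if (length(corRows)) do.call(rbind, corRows) else
    data.frame()
  sampleSizes <- if (length(ssRows)) do.call(rbind, ssRows) else
    data.frame()

  settings <- cfg
  if (isTRUE(cfg$dlaSensitivity)) {
    settings$dlaBlock <- dlaMatrixSizeExperiment(
      replicates = cfg$dlaReplicates, seed = cfg$seed,
      rThreshold = cfg$rThreshold, nMax = cfg$nMax)
  }

  report <- new("CohortReport", fdTable = fdTable,
                summaryTable = contrasts$summary,
                pairedTests = contrasts$paired,
                correlations = correlations, sampleSizes = sampleSizes,
                subjects = subjects, settings = settings)
  if (!is.null(cfg$outputDir)) .writeReport(report, cfg$outputDir)
  report
}

.writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report@fdTable, file.path(dir, "report.csv"),
            row.names = FALSE)
  write.csv(report@correlations, file.path(dir, "correlations.csv"),
            row.names = FALSE)
  con <- file(file.path(dir, "summary.txt"), "w")
  on.exit(close(con))
  s <- report@summaryTable
  writeLines("Group means +/- SEM", con)
  for (i in seq_len(nrow(s)))
    writeLines(sprintf("  %-8s %-6s %-3s %.4f +/- %.4f (n=%d)",
                       s$group[i], s$region[i], s$method[i], s$mean[i],
                       s$sem[i], s$n[i]), con)
  writeLines("Correlations (AVM-side FD vs covariate)", con)
  cr <- report@correlations
  for (i in seq_len(nrow(cr)))
    writeLines(sprintf("  %-3s vs %-13s r = %.3f, p = %.3g, n = %d",
                       cr$method[i], cr$covariate[i], cr$r[i], cr$p[i],
                       cr$n[i]), con)
  writeLines("Fisher-z sample sizes", con)
  ss <- report@sampleSizes
  for (i in seq_len(nrow(ss)))
    writeLines(sprintf("  %-3s vs %-13s n = %d", ss$method[i],
                       ss$covariate[i], ss$n[i]), con)
  invisible(dir)
}
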