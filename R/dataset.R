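#' Construct a time-course dataset
#'
#' @param data data.frame with columns condition, readout, time_min, mean,
#'   sem, n_reps (one row per condition x readout x time).
#' @return A [TimeCourseDataset-class] object.
#' @export
timeCourseDataset <- function(data) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  obj <- new("TimeCourseDataset", data = data)
  obj
}

#' @export
#' @describeIn timeCourseDataset Extract the underlying tidy data.frame.
#' @param x A [TimeCourseDataset-class] object.
tcData <- function(x) x@data

#' @export
setMethod("show", "TimeCourseDataset", function(object) {
  d <- object@data
  cat(sprintf("TimeCourseDataset: %d records, %d condition(s), %d readout(s), %d time point(s)\n",
              nrow(d), length(unique(d$condition)),
              length(unique(d$readout)), length(unique(d$time_min))))
})

#' @export
setMethod("as.data.frame", "TimeCourseDataset",
          function(x, row.names = NULL, optional = FALSE, ...) x@data)

# run expr with a temporary RNG state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic immunoblot time-course dataset
#'
#' Simulates the model under each condition, multiplies each replicate's
#' observable trajectory pointwise by i.i.d. multiplicative noise
#' (log-normal, unit mean, coefficient of variation `cv`; optionally additive
#' Gaussian), then normalizes each replicate to its own mean across the time
#' course — emulating the per-replicate normalization applied to quantified
#' immunoblot intensities. Means and SEMs are taken across replicates.
#'
#' @param model An [MTORModel-class] object.
#' @param params Named parameter vector (natural scale).
#' @param conditions A [StressCondition-class] or list of them.
#' @param times Sampling grid (minutes), starting at 0.
#' @param nReps Replicates per condition.
#' @param cv Coefficient of variation of the replicate noise (0 = noise-free).
#' @param seed Integer seed; generation is reproducible given the seed.
#' @param normalize Per-replicate mean-normalization (default TRUE; FALSE
#'   yields raw observable concentrations, useful for recovery studies).
#' @param noise "lognormal" (default; intensities are positive and roughly
#'   scale-proportional) or "gaussian" (additive, sd = cv * value).
#' @return A [TimeCourseDataset-class] object.
#' @export
#' @examples
#' m <- buildModel("V")
#' ds <- generateDataset(m, groundTruthParams(), m@conditions$arsenite,
#'                       nReps = 4, cv = 0.15, seed = 1)
generateDataset <- function(model, params, conditions,
                            times = defaultTimes(), nReps = 4, cv = 0.15,
                            seed = 1, normalize = TRUE,
                            noise = c("lognormal", "gaussian")) {
  noise <- match.arg(noise)
  stopifnot(nReps >= 1, cv >= 0, cv < 1)
  if (is(conditions, "StressCondition")) conditions <- list(conditions)
  .withSeed(seed, {
    recs <- lapply(conditions, function(cond) {
      traj <- simulateModel(model, cond, params, times = times)
      om <- .observableMatrix(traj)    # times x 9
      reps <- array(NA_real_, c(nrow(om), ncol(om), nReps))
      for (r in seq_len(nReps)) {
        if (cv > 0 && noise == "lognormal") {
          sdlog <- sqrt(log(1 + cv^2))
          fac <- matrix(stats::rlnorm(length(om), -sdlog^2 / 2, sdlog),
                        nrow(om))
          v <- om * fac
        } else if (cv > 0) {
          v <- pmax(om + matrix(stats::rnorm(length(om), 0, cv) , nrow(om)) *
                      om, 0)
        } else v <- om
        if (normalize) {
          mns <- colMeans(v)
          mns[mns <= 0] <- 1           # all-zero readout: leave untouched
          v <- sweep(v, 2, mns, "/")
        }
        reps[, , r] <- v
      }
      mn <- apply(reps, c(1, 2), mean)
      sem <- if (nReps > 1)
        apply(reps, c(1, 2), stats::sd) / sqrt(nReps)
      else matrix(0, nrow(om), ncol(om))
      data.frame(condition = cond@label,
                 readout = rep(colnames(om), each = nrow(om)),
                 time_min = rep(times, times = ncol(om)),
                 mean = as.vector(mn), sem = as.vector(sem),
                 n_reps = nReps, stringsAsFactors = FALSE)
    })
    timeCourseDataset(do.call(rbind, c(recs, list(make.row.names = FALSE))))
  })
}

#' Derive the artificial no-stress companion dataset
#'
#' Replaces every record's mean (and SEM) by the corresponding t = 0 value
#' and relabels the condition with a `_no_stress` suffix. Fitted alongside
#' the real data, such constant companions penalize artificial dynamic
#' behaviour of the model in the absence of stress. Idempotent.
#'
#' @param template A [TimeCourseDataset-class] with a t = 0 record per
#'   (condition, readout).
#' @return A [TimeCourseDataset-class] object.
#' @export
makeConstantDataset <- function(template) {
  out <- tcData(template)
  key <- paste(out$condition, out$readout, sep = "\r")
  i0 <- match(key, key[out$time_min == 0])
  if (anyNA(i0)) {
    bad <- unique(key[is.na(i0)])[1]
    stop(sprintf("missing t = 0 record for (%s)",
                 gsub("\r", ", ", bad)), call. = FALSE)
  }
  anchor <- which(out$time_min == 0)[i0]
  out$mean <- out$mean[anchor]
  out$sem <- out$sem[anchor]
  out$n_reps <- out$n_reps[anchor]
  plain <- !grepl("_no_stress$", out$condition)
  out$condition[plain] <- paste0(out$condition[plain], "_no_stress")
  timeCourseDataset(out)
}

#' Restrict a wortmannin dataset to the stress-input residual readouts
#'
#' Under full PI3K inhibition, remaining induction of Akt-pS473,
#' p70-S6K-pT389, 4E-BP1-pT37/46 and PRAS40-pS183 must be attributed to
#' PI3K-independent inputs. The returned dataset contains only these four
#' readouts under wortmannin conditions and carries the attribute
#' `purpose = "input_strength_constraint"`: it is fitted with only the
#' stress-input strength parameters free, to narrow their solution space.
#'
#' @param wortmanninDs A [TimeCourseDataset-class] containing wortmannin
#'   condition(s) covering the four readouts.
#' @return A restricted [TimeCourseDataset-class] object.
#' @export
wortmanninResidualDataset <- function(wortmanninDs) {
  keep <- c("Akt_pS473", "p70_S6K_pT389", "4EBP1_pT37_46", "PRAS40_pS183")
  d <- tcData(wortmanninDs)
  d <- d[grepl("wortmannin", d$condition), , drop = FALSE]
  if (!all(keep %in% unique(d$readout)))
    stop("wortmannin dataset must cover the readouts ",
         paste(keep, collapse = ", "), call. = FALSE)
  d <- d[d$readout %in% keep, , drop = FALSE]
  rownames(d) <- NULL
  out <- timeCourseDataset(d)
  attr(out, "purpose") <- "input_strength_constraint"
  out
}

#' Read / write time-course datasets
#'
#' Plain CSV with header `condition,readout,time_min,mean,sem,n_reps`;
#' round-trips losslessly to full double precision.
#'
#' @param path CSV file path.
#' @return [readTimeCourse()]: a [TimeCourseDataset-class] object.
#' @export
readTimeCourse <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "readout", "time_min", "mean", "sem", "n_reps")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  dup <- duplicated(d[c("condition", "readout", "time_min")])
  if (any(dup))
    stop(sprintf("%s: duplicate (condition, readout, time) at row(s) %s",
                 path, paste(which(dup), collapse = ", ")), call. = FALSE)
  bad <- which(d$sem < 0 | d$mean < 0 | d$n_reps < 1)
  if (length(bad))
    stop(sprintf("%s: invalid mean/sem/n_reps at row(s) %s", path,
                 paste(bad, collapse = ", ")), call. = FALSE)
  timeCourseDataset(d)
}

#' @rdname readTimeCourse
#' @param ds A [TimeCourseDataset-class] object.
#' @export
writeTimeCourse <- function(ds, path) {
  d <- tcData(ds)
  # full precision so that write -> read is lossless
  for (col in c("time_min", "mean", "sem"))
    d[[col]] <- formatC(d[[col]], format = "g", digits = 17)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bind several datasets into one
#' @param ... [TimeCourseDataset-class] objects.
#' @export
bindDatasets <- function(...) {
  timeCourseDataset(do.call(rbind, c(lapply(list(...), tcData),
                                     list(make.row.names = FALSE))))
}
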