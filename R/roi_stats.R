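resolve_roi <- function(atlas, roi) {
  tab <- atlas$roi_table
  row <- if (is.numeric(roi)) tab[tab$code == roi, ] else tab[tab$name == roi, ]
  if (nrow(row) != 1) stop("unknown ROI '", roi, "'")
  row
}

#' Summarize low-frequency conductivity inside one ROI
#'
#' Median and interquartile range of sigma_L over the valid voxels of one
#' region. Quartiles use linear interpolation between order statistics
#' (\code{quantile} type 7), the common convention in scientific software.
#'
#' @param sigma a \code{conductivity_volume} from [sigma_low()].
#' @param atlas the \code{tissue_atlas} the volume was computed on.
#' @param roi ROI code or name.
#' @return one-row data.frame: \code{roi_code}, \code{roi_name},
#'   \code{tissue}, \code{n_voxels}, \code{median}, \code{q1}, \code{q3},
#'   \code{iqr} (conductivities in S/m).
#' @export
summarize_roi <- function(sigma, atlas, roi) {
  row <- resolve_roi(atlas, roi)
  sel <- atlas$roi_labels == row$code & sigma$valid_mask
  vals <- sigma$sigma_L[sel]
  if (length(vals) == 0) {
    stop("summarize_roi: ROI '", row$name, "' contains no valid voxels")
  }
  q <- unname(quantile(vals, c(0.25, 0.5, 0.75), type = 7))
  data.frame(roi_code = row$code, roi_name = row$name, tissue = row$tissue,
             n_voxels = length(vals), median = q[2], q1 = q[1], q3 = q[3],
             iqr = q[3] - q[1], stringsAsFactors = FALSE)
}

#' Shapiro-Wilk normality screen
#'
#' Screens a vector of per-subject ROI medians for normality at level
#' \code{alpha}; the verdict is "non-normal" when p < alpha. A
#' zero-variance sample is degenerate for the test and is reported as
#' non-normal with \code{degenerate = TRUE}.
#'
#' @param values numeric vector, n >= 3.
#' @param alpha significance level (default 0.05).
#' @return list with \code{statistic}, \code{p_value}, \code{verdict}
#'   ("normal"/"non-normal") and \code{degenerate}.
#' @export
normality_screen <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3) {
    stop("normality_screen: need at least 3 observations, got ",
         length(values))
  }
  if (diff(range(values)) == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                verdict = "non-normal", degenerate = TRUE))
  }
  sw <- shapiro.test(values)
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       verdict = if (sw$p.value < alpha) "non-normal" else "normal",
       degenerate = FALSE)
}

#' Per-subject, per-ROI conductivity table for a cohort
#'
#' Runs the full conversion for every subject of a synthetic cohort —
#' microstructure parameters to CTI maps ([cti_from_params()]), then to
#' low-frequency conductivity ([sigma_low()]) — and summarizes every ROI
#' ([summarize_roi()]). Low-frequency CSF conductivity is not a meaningful
#' output of the conversion, so ROIs whose tissue class is CSF are excluded
#' by default (the default atlas has none).
#'
#' @param cohort a \code{phantom_cohort} from [generate_cohort()].
#' @param atlas the matching \code{tissue_atlas}.
#' @param sigma_h a \code{sigma_h_atlas} from [build_sigma_h()].
#' @param config a [cti_config()].
#' @param exclude_csf drop CSF-class ROIs (default TRUE).
#' @param ... passed to the model adapter (e.g. \code{scaling} for NODDI).
#' @return data.frame of class \code{cohort_table}: one row per
#'   (subject, ROI) with the [summarize_roi()] columns plus \code{subject}
#'   and \code{model}.
#' @export
cohort_table <- function(cohort, atlas, sigma_h, config = cti_config(),
                         exclude_csf = TRUE, ...) {
  stopifnot(inherits(cohort, "phantom_cohort"),
            inherits(atlas, "tissue_atlas"),
            inherits(sigma_h, "sigma_h_atlas"))
  rois <- atlas$roi_table
  if (exclude_csf) rois <- rois[rois$tissue != "CSF", ]
  out <- vector("list", length(cohort$subjects))
  for (k in seq_along(cohort$subjects)) {
    subj <- names(cohort$subjects)[k]
    rows <- tryCatch({
      cti <- cti_from_params(cohort$subjects[[k]], cohort$model, ...)
      sig <- sigma_low(cti, sigma_h, config)
      do.call(rbind, lapply(rois$code,
                            function(code) summarize_roi(sig, atlas, code)))
    }, error = function(e) {
      stop("cohort_table: subject ", subj, ": ", conditionMessage(e),
           call. = FALSE)
    })
    rows$subject <- subj
    rows$model <- cohort$model
    out[[k]] <- rows
  }
  tab <- do.call(rbind, out)
  tab <- tab[, c("subject", "model", "roi_code", "roi_name", "tissue",
                 "n_voxels", "median", "q1", "q3", "iqr")]
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Normality screen over a cohort table
#'
#' Applies [normality_screen()] to the per-subject medians of every
#' (ROI, model) cell of a cohort table.
#'
#' @param table a \code{cohort_table}.
#' @param alpha significance level.
#' @return data.frame with one row per ROI x model:
#'   \code{model}, \code{roi_name}, \code{n}, \code{statistic},
#'   \code{p_value}, \code{verdict}, \code{degenerate}.
#' @export
screen_normality <- function(table, alpha = 0.05) {
  cells <- unique(table[, c("model", "roi_name")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- table$model == cells$model[i] & table$roi_name == cells$roi_name[i]
    ns <- if (sum(sel) < 3) {
      # too few subjects for the test; recorded, not an error, so that small
      # smoke-test cohorts still produce a complete table
      list(statistic = NA_real_, p_value = NA_real_,
           verdict = "insufficient-n", degenerate = NA)
    } else {
      normality_screen(table$median[sel], alpha)
    }
    data.frame(model = cells$model[i], roi_name = cells$roi_name[i],
               n = sum(sel), statistic = ns$statistic, p_value = ns$p_value,
               verdict = ns$verdict, degenerate = ns$degenerate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Box-plot summary of per-subject ROI medians
#'
#' Group-level summary of the per-subject medians in each (ROI, model) cell:
#' median, quartiles, and whiskers at the most extreme observations within
#' 1.5 x IQR of the quartiles (Tukey fences).
#'
#' @param table a \code{cohort_table}.
#' @return data.frame with one row per ROI x model.
#' @export
boxplot_summary <- function(table) {
  cells <- unique(table[, c("model", "roi_name", "tissue")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- table$model == cells$model[i] & table$roi_name == cells$roi_name[i]
    v <- table$median[sel]
    q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
    iqr <- q[3] - q[1]
    inside <- v[v >= q[1] - 1.5 * iqr & v <= q[3] + 1.5 * iqr]
    data.frame(model = cells$model[i], roi_name = cells$roi_name[i],
               tissue = cells$tissue[i], n = length(v),
               median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
               whisker_low = min(inside), whisker_high = max(inside),
               n_outliers = length(v) - length(inside),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
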