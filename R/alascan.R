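#' ELISA binding curve
#'
#' One concentration series with A450 signals for one mutant. Concentrations
#' must be strictly positive; points are re-ordered ascending.
#'
#' @param mutant_id mutant label (e.g. `"Y124A"`, `"WT"`).
#' @param concentrations numeric, all > 0.
#' @param signals A450 absorbances, same length.
#' @param unit concentration unit, recorded only (`"ug/mL"` or `"nM"`).
#' @param replicate_id optional replicate label.
#' @return object of class `binding_curve`.
#' @export
binding_curve <- function(mutant_id, concentrations, signals,
                          unit = "ug/mL", replicate_id = NULL) {
  .assert(length(concentrations) == length(signals), "length mismatch")
  .assert(all(concentrations > 0), "concentrations must be strictly positive")
  o <- order(concentrations)
  structure(list(mutant_id = mutant_id, concentrations = concentrations[o],
                 signals = signals[o], unit = unit, replicate_id = replicate_id),
            class = "binding_curve")
}

#' Fit a four-parameter logistic binding model
#'
#' Least-squares fit of `signal = bottom + (top - bottom)/(1 + (ec50/x)^hill)`
#' to a dilution series, via Levenberg-Marquardt (minpack.lm). The EC50 of the
#' indirect ELISA serves as the apparent Kd. Initialisation: bottom = min
#' signal, top = max signal, hill = 1, ec50 = concentration nearest the
#' half-range signal; hill is bounded to [0.2, 5]. The fit is reported as
#' non-converged when the optimizer fails, the curve is flat, the fitted
#' EC50 falls outside a tenth of the lowest to ten times the highest tested
#' concentration (no plateau observed on that side), or the dose-response
#' model fails to explain at least 80% of the signal variance, or the fitted
#' amplitude does not rise clearly above noise and background (a flat noisy
#' curve carries no EC50 information even when the optimizer returns one).
#'
#' @param curve a [binding_curve()] (>= 4 points).
#' @param max_iter maximum optimizer iterations.
#' @return object of class `fourpl_fit`: `bottom`, `top`, `ec50`, `hill`,
#'   `kd_estimate` (= ec50), `converged`, `residual_sd`, `mutant_id`.
#' @export
fit_4pl <- function(curve, max_iter = 200L) {
  .assert(inherits(curve, "binding_curve"), "curve must be a binding_curve")
  x <- curve$concentrations; y <- curve$signals
  .assert(length(x) >= 4, "need at least 4 points to fit a 4PL")
  fail <- function() structure(list(bottom = NA_real_, top = NA_real_,
                                    ec50 = NA_real_, hill = NA_real_,
                                    kd_estimate = NA_real_, converged = FALSE,
                                    residual_sd = NA_real_,
                                    mutant_id = curve$mutant_id),
                               class = "fourpl_fit")
  rng <- diff(range(y))
  if (rng < 1e-6) return(fail()) # flat curve carries no dose information
  half <- min(y) + rng / 2
  start <- list(bottom = min(y), top = max(y),
                ec50 = x[which.min(abs(y - half))], hill = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ bottom + (top - bottom) / (1 + (ec50 / x)^hill),
                      start = start,
                      lower = c(bottom = -Inf, top = -Inf, ec50 = min(x) * 1e-4,
                                hill = 0.2),
                      upper = c(bottom = Inf, top = Inf, ec50 = max(x) * 1e4,
                                hill = 5),
                      control = minpack.lm::nls.lm.control(maxiter = max_iter)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail())
  p <- as.list(stats::coef(fit))
  rss_fit <- sum(stats::residuals(fit)^2)
  rss_const <- sum((y - mean(y))^2)
  converged <- p$top > p$bottom &&
    p$ec50 >= min(x) / 10 && p$ec50 <= max(x) * 10 &&
    rss_fit < 0.2 * rss_const &&
    # the fitted dynamic range must clear the residual noise decisively and
    # rise well above the background level, otherwise the "curve" is noise
    # dressed up as dose-response (appropriate for indirect-ELISA signals,
    # which climb several-fold over background when binding is real)
    (p$top - p$bottom) > 6 * stats::sigma(fit) &&
    (p$top - p$bottom) > mean(y)
  structure(list(bottom = p$bottom, top = p$top, ec50 = p$ec50, hill = p$hill,
                 kd_estimate = p$ec50, converged = converged,
                 residual_sd = stats::sigma(fit), mutant_id = curve$mutant_id),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat("4PL fit", if (!is.null(x$mutant_id)) paste0("[", x$mutant_id, "]"),
      if (x$converged) sprintf(": ec50 %.4g, hill %.3g, range [%.3g, %.3g]\n",
                               x$ec50, x$hill, x$bottom, x$top)
      else ": not converged\n")
  invisible(x)
}

#' Fold-decrease bin classification
#'
#' The asterisk legend used for scan read-outs: below 2-fold, no mark
#' (`none`); 2 to 10-fold, `*` (`star`); above 10 to 100-fold, `**` (`star2`);
#' above 100-fold or censored, `***` (`star3`). Improvements (fold < 1) fall
#' in `none`.
#'
#' @param fold numeric fold decrease(s), >= 0.
#' @param censored logical, recycled; censored records go to `star3`.
#' @return ordered factor with levels `none < star < star2 < star3`.
#' @export
classify_bins <- function(fold, censored = FALSE) {
  censored <- rep_len(censored, length(fold))
  .assert(all(censored | fold >= 0), "negative fold change")
  lab <- ifelse(censored | fold > 100, "star3",
         ifelse(fold > 10, "star2",
         ifelse(fold >= 2, "star", "none")))
  factor(lab, levels = c("none", "star", "star2", "star3"), ordered = TRUE)
}

#' Fold change of a mutant relative to wild type
#'
#' `kd_ratio` mode compares apparent Kd values of 4PL fits
#' (`fold = kd_mut / kd_wt`); a non-converged mutant fit means binding was
#' knocked out beyond the measurable range and is censored at `censor_bound`
#' (reported as `">bound"`, bin `star3`, never as a number). `spot_a450` mode
#' compares single-concentration absorbances (`fold = A450_wt / A450_mut`).
#'
#' @param mutant,wildtype `fourpl_fit` objects (kd_ratio mode) or single
#'   numeric A450 signals (spot_a450 mode).
#' @param mode `"kd_ratio"` or `"spot_a450"`.
#' @param censor_bound censoring bound for unmeasurable folds (default 100).
#' @param mutant_id label override (defaults to the mutant fit's id).
#' @return a `fold_change_record`: one-row data.frame with `mutant_id`,
#'   `mode`, `fold`, `censored`, `censor_bound`, `bin`.
#' @export
fold_change <- function(mutant, wildtype, mode = c("kd_ratio", "spot_a450"),
                        censor_bound = 100, mutant_id = NULL) {
  mode <- match.arg(mode)
  if (mode == "kd_ratio") {
    .assert(inherits(wildtype, "fourpl_fit") && wildtype$converged,
            "wild-type fit must be converged")
    mutant_id <- mutant_id %||% mutant$mutant_id
    if (!mutant$converged) {
      fold <- NA_real_; censored <- TRUE
    } else {
      fold <- mutant$kd_estimate / wildtype$kd_estimate; censored <- FALSE
    }
  } else {
    .assert(is.numeric(wildtype) && wildtype > 0, "wild-type signal must be > 0")
    .assert(is.numeric(mutant), "mutant signal must be numeric")
    if (mutant <= 0) { fold <- NA_real_; censored <- TRUE }
    else { fold <- wildtype / mutant; censored <- FALSE }
    if (!censored && fold > censor_bound) { fold <- NA_real_; censored <- TRUE }
  }
  rec <- data.frame(mutant_id = mutant_id %||% NA_character_, mode = mode,
                    fold = fold, censored = censored,
                    censor_bound = censor_bound, stringsAsFactors = FALSE)
  rec$bin <- classify_bins(ifelse(censored, censor_bound + 1, fold), censored)
  class(rec) <- c("fold_change_record", "data.frame")
  rec
}

#' Hotspot table
#'
#' Collects fold-change records (one per tested residue mutation) and marks
#' hotspots: records whose bin is at least `hotspot_threshold_bin`.
#'
#' @param records a data.frame of fold-change records (rows rbind-able from
#'   [fold_change()]), with `mutant_id` unique.
#' @param hotspot_threshold_bin minimum bin for hotspot status (default
#'   `"star2"`, i.e. more than 10-fold).
#' @return a `hotspot_table` (data.frame with logical column `hotspot`).
#' @export
hotspot_table <- function(records, hotspot_threshold_bin = "star2") {
  .assert(!anyDuplicated(records$mutant_id), "duplicate mutant_id in records")
  records$bin <- factor(as.character(records$bin),
                        levels = c("none", "star", "star2", "star3"),
                        ordered = TRUE)
  records$hotspot <- records$bin >= hotspot_threshold_bin
  attr(records, "hotspot_threshold_bin") <- hotspot_threshold_bin
  class(records) <- c("hotspot_table", "data.frame")
  records
}

#' Build epitope restraint scenarios
#'
#' One docking scenario per labelled epitope hotspot group, plus a combined
#' scenario (union of all groups, deduplicated); the paratope restraint set is
#' held constant across scenarios. With a single group the combined scenario
#' coincides with it and is not duplicated.
#'
#' @param epitope_groups named list of character vectors of antigen residue
#'   keys (e.g. `list(D2 = c("A:52", "A:124"), ...)`).
#' @param paratope_hotspots character vector of antibody residue keys.
#' @return list of `restraint_scenario` objects (`name`, `epitope_active`,
#'   `paratope_active`).
#' @export
build_scenarios <- function(epitope_groups, paratope_hotspots) {
  .assert(length(epitope_groups) >= 1, "need at least one epitope group")
  .assert(length(paratope_hotspots) >= 1, "paratope set must be non-empty")
  .assert(all(vapply(epitope_groups, length, 1L) > 0), "empty epitope group")
  mk <- function(name, ep) structure(
    list(name = name, epitope_active = unique(ep),
         paratope_active = unique(paratope_hotspots)),
    class = "restraint_scenario")
  nms <- names(epitope_groups) %||% paste0("scenario", seq_along(epitope_groups))
  out <- Map(mk, nms, epitope_groups)
  combined <- unique(unlist(epitope_groups, use.names = FALSE))
  if (length(epitope_groups) > 1) out <- c(out, list(combined = mk("combined", combined)))
  unname(out)
}

#' Export a restraint scenario
#'
#' Writes the active-residue lists in the plain-text form used for
#' docking-server submission: one `antigen_active:` and one
#' `antibody_active:` line of comma-separated `chain:resnum` entries, in
#' deterministic (sorted) order.
#'
#' @param scenario a `restraint_scenario` from [build_scenarios()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
export_restraints <- function(scenario, path) {
  .assert(inherits(scenario, "restraint_scenario"), "not a restraint_scenario")
  .assert(length(scenario$epitope_active) > 0, "empty epitope set")
  .assert(length(scenario$paratope_active) > 0, "empty paratope set")
  srt <- function(k) {
    p <- parse_residue_key(k)
    k[order(p$chain, p$resno, p$icode)]
  }
  lines <- c(paste0("name: ", scenario$name),
             paste0("antigen_active: ", paste(srt(scenario$epitope_active), collapse = ",")),
             paste0("antibody_active: ", paste(srt(scenario$paratope_active), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Read back an exported restraint scenario
#'
#' @param path file written by [export_restraints()].
#' @return a `restraint_scenario`.
#' @export
read_restraints <- function(path) {
  lines <- readLines(path)
  get <- function(tag) {
    l <- sub(paste0("^", tag, ": "), "", grep(paste0("^", tag, ": "), lines, value = TRUE))
    .assert(length(l) == 1, "missing '", tag, "' line in ", path)
    l
  }
  structure(list(name = get("name"),
                 epitope_active = strsplit(get("antigen_active"), ",")[[1]],
                 paratope_active = strsplit(get("antibody_active"), ",")[[1]]),
            class = "restraint_scenario")
}

#' Read an ELISA panel CSV
#'
#' Expected columns: `mutant_id`, `concentration`, `unit`, `a450`, optional
#' `replicate`. Returns one [binding_curve()] per mutant, pooling replicates
#' (replicate ids retained).
#'
#' @param path CSV path.
#' @return named list of `binding_curve` objects.
#' @export
read_elisa_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mutant_id", "concentration", "unit", "a450")
  .assert(all(need %in% names(d)), "ELISA CSV needs columns: ",
          paste(need, collapse = ", "))
  lapply(split(d, d$mutant_id), function(g)
    binding_curve(g$mutant_id[1], g$concentration, g$a450, unit = g$unit[1],
                  replicate_id = if ("replicate" %in% names(d)) g$replicate else NULL))
}

#' Alanine-scan analysis of an ELISA panel
#'
#' Fits every curve, computes Kd-ratio fold changes against `"WT"`, bins and
#' marks hotspots. The full scan step in one call.
#'
#' @param curves named list of [binding_curve()]s including `"WT"`.
#' @param censor_bound censoring bound (default 100).
#' @param hotspot_threshold_bin minimum hotspot bin (default `"star2"`).
#' @return a `hotspot_table` with extra column `kd`.
#' @export
analyze_scan <- function(curves, censor_bound = 100,
                         hotspot_threshold_bin = "star2") {
  .assert("WT" %in% names(curves), "panel must include a 'WT' curve")
  fits <- lapply(curves, fit_4pl)
  wt <- fits[["WT"]]
  .assert(wt$converged, "wild-type curve did not converge")
  recs <- do.call(rbind, lapply(names(fits), function(id) {
    r <- fold_change(fits[[id]], wt, mode = "kd_ratio", censor_bound = censor_bound)
    r$kd <- if (fits[[id]]$converged) fits[[id]]$kd_estimate else NA_real_
    r
  }))
  hotspot_table(recs[recs$mutant_id != "WT", , drop = FALSE],
                hotspot_threshold_bin = hotspot_threshold_bin)
}
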