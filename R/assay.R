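#' Rotenone-sensitive complex I activity from A340 kinetic traces
#'
#' Complex I oxidizes NADH, which absorbs at 340 nm, so activity appears as
#' a declining A340 trace; the rotenone-insensitive background is removed by
#' subtracting the slope measured with 1 uM rotenone. Each trace's rate is
#' the least-squares slope over the analysis window; the reported activity
#' is `|slope_minus_rotenone - slope_plus_rotenone|` in delta-A340 per
#' minute (NADH consumption gives negative slopes; activity is positive by
#' convention).
#'
#' @param minus_rot,plus_rot Data frames with numeric columns `time`
#'   (seconds, strictly increasing) and `a340`.
#' @param window Length-2 numeric, analysis window in seconds; default the
#'   first 10 minutes (initial-rate convention).
#' @return List with `activity` (delta A340/min), `slope_minus`,
#'   `slope_plus` (each in delta A340/min), and `n_points` used per trace.
#' @export
complex1_activity <- function(minus_rot, plus_rot, window = c(0, 600)) {
  slope_per_min <- function(tr, label) {
    if (!all(c("time", "a340") %in% names(tr)))
      stop(label, " trace needs 'time' and 'a340' columns")
    if (nrow(tr) < 5L) stop(label, " trace needs at least 5 points")
    if (any(diff(tr$time) <= 0)) stop(label, " trace time must be strictly increasing")
    if (window[1] < min(tr$time) - 1e-9 || window[2] > max(tr$time) + 1e-9)
      stop("analysis window [", window[1], ", ", window[2],
           "] s outside ", label, " trace")
    sel <- tr$time >= window[1] & tr$time <= window[2]
    if (sum(sel) < 3L) stop("fewer than 3 points in window for ", label)
    fit <- stats::lm.fit(cbind(1, tr$time[sel]), tr$a340[sel])
    list(slope = unname(fit$coefficients[2]) * 60, n = sum(sel))
  }
  m <- slope_per_min(minus_rot, "minus-rotenone")
  p <- slope_per_min(plus_rot, "plus-rotenone")
  list(activity = abs(m$slope - p$slope),
       slope_minus = m$slope, slope_plus = p$slope,
       n_points = c(minus = m$n, plus = p$n))
}

#' Blue-native PAGE supercomplex and subcomplex ratios
#'
#' Band intensities per sample are reduced to two ratios against the
#' fully-assembled complex I band: `SC_ratio = supercomplex / assembled_CI`
#' and `sub_ratio = subcomplex / assembled_CI` (subcomplexes are species
#' smaller than assembled complex I). Each ratio is also normalized to the
#' control sample's ratio, so the control is exactly 1.
#'
#' @param bands Data frame with columns `sample_id`, `band_class` (one of
#'   `supercomplex`, `assembled_CI`, `subcomplex`, `other`), `intensity`
#'   (>= 0); one row per (sample, class).
#' @param control_id Sample id of the non-targeting control lane.
#' @return Data frame per sample: `sample_id`, `SC_ratio`, `sub_ratio`,
#'   `SC_norm`, `sub_norm` (`NA` where a band class is absent).
#' @export
bnpage_ratios <- function(bands, control_id) {
  stopifnot(all(c("sample_id", "band_class", "intensity") %in% names(bands)))
  if (any(bands$intensity < 0)) stop("negative band intensity")
  if (anyDuplicated(bands[, c("sample_id", "band_class")]))
    stop("duplicate (sample, band_class) rows")
  get <- function(s, cls) {
    v <- bands$intensity[bands$sample_id == s & bands$band_class == cls]
    if (length(v) == 0L) NA_real_ else v
  }
  samples <- unique(bands$sample_id)
  if (!control_id %in% samples) stop("control sample '", control_id, "' absent")
  ratio <- function(s) {
    ci <- get(s, "assembled_CI")
    if (is.na(ci) || ci <= 0)
      stop("sample '", s, "' lacks a positive assembled_CI band")
    sc <- get(s, "supercomplex"); sub <- get(s, "subcomplex")
    if (is.na(sc)) warning("sample '", s, "' missing supercomplex band")
    if (is.na(sub)) warning("sample '", s, "' missing subcomplex band")
    c(SC = sc / ci, sub = sub / ci)
  }
  rr <- t(vapply(samples, ratio, numeric(2)))
  ctrl <- rr[control_id == samples, ]
  data.frame(sample_id = samples,
             SC_ratio = rr[, "SC"], sub_ratio = rr[, "sub"],
             SC_norm = rr[, "SC"] / ctrl["SC"],
             sub_norm = rr[, "sub"] / ctrl["sub"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicate Ct values are averaged on the Ct scale per
#' (sample, gene); then `dCt_s = Ct_target,s - Ct_reference,s`,
#' `ddCt_s = dCt_s - dCt_control`, and the fold change is `2^-ddCt`.
#' A knockdown halving transcript abundance gives fold 0.5.
#'
#' @param cts Data frame with columns `sample_id`, `gene`, `ct`
#'   (0 < ct <= 40), and optionally `replicate`.
#' @param control_sample Sample id of the reference (e.g. non-targeting)
#'   sample.
#' @param reference_gene Gene used as endogenous control (e.g. `"ACTB"`);
#'   every other gene is treated as a target.
#' @return Data frame: `sample_id`, `gene` (target), `dct`, `ddct`, `fold`.
#' @export
ddct_fold <- function(cts, control_sample, reference_gene = "reference") {
  stopifnot(all(c("sample_id", "gene", "ct") %in% names(cts)))
  if (any(cts$ct <= 0 | cts$ct > 40)) stop("Ct values must lie in (0, 40]")
  agg <- stats::aggregate(ct ~ sample_id + gene, data = cts, FUN = mean)
  ref <- agg[agg$gene == reference_gene, ]
  if (!nrow(ref)) stop("reference gene '", reference_gene, "' absent")
  targets <- agg[agg$gene != reference_gene, ]
  if (!control_sample %in% agg$sample_id)
    stop("control sample '", control_sample, "' absent")
  ref_ct <- stats::setNames(ref$ct, ref$sample_id)
  if (any(!targets$sample_id %in% names(ref_ct)))
    stop("missing reference gene Ct for sample(s): ",
         paste(setdiff(targets$sample_id, names(ref_ct)), collapse = ", "))
  targets$dct <- targets$ct - ref_ct[targets$sample_id]
  out <- do.call(rbind, lapply(split(targets, targets$gene), function(tg) {
    if (!control_sample %in% tg$sample_id)
      stop("control sample lacks target gene '", tg$gene[1], "'")
    d0 <- tg$dct[tg$sample_id == control_sample]
    tg$ddct <- tg$dct - d0
    tg$fold <- 2^(-tg$ddct)
    tg
  }))
  rownames(out) <- NULL
  out[, c("sample_id", "gene", "dct", "ddct", "fold")]
}
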