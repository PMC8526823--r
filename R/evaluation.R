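## Confusion-table arithmetic against reference labels, plus the built-in
## fixture that encodes the reference study's published per-rule counts
## (31 progressing patients, 45 stable patients, 28 healthy controls).

#' Round half-up to a number of decimals
#'
#' Plain decimal rounding with ties away from zero (the convention used in
#' clinical tables), unlike base R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

rule_flags <- function(calls, rule) {
  col <- switch(rule,
                ONH = "flag_onh", MAC = "flag_mac", OR = "flag_or",
                AND = "flag_and", FIXED5 = "flag_5um",
                stop("unknown rule: ", rule))
  if (!col %in% names(calls)) stop("calls are missing column ", col)
  calls[[col]]
}

#' Confusion table of one progression rule
#'
#' Counts false negatives among truly progressing patients (`RS-P`),
#' false positives among stable patients (`RS-NP`) and among healthy
#' controls (`HC`), and the accuracy over the patient eyes only (healthy
#' controls are reported separately). Rates are percentages rounded
#' half-up to one decimal.
#'
#' @param calls Data frame of per-eye flags (see [classify_cohort()] or
#'   [paper_fixture()]).
#' @param labels Character vector (same order as `calls`) with values in
#'   `RS-P`, `RS-NP`, `HC`.
#' @param rule `"ONH"`, `"MAC"`, `"OR"`, `"AND"` or `"FIXED5"`.
#' @return One-row data frame: rule, stratum sizes, FN/FP counts and
#'   rates, and patient accuracy (%).
#' @export
confusion <- function(calls, labels, rule) {
  if (length(labels) != nrow(calls))
    stop("`labels` must have one entry per call")
  if (!all(labels %in% c("RS-P", "RS-NP", "HC")))
    stop("labels must be RS-P, RS-NP or HC")
  flags <- rule_flags(calls, rule)
  n_rsp <- sum(labels == "RS-P")
  n_rsnp <- sum(labels == "RS-NP")
  n_hc <- sum(labels == "HC")
  fn <- sum(labels == "RS-P" & !flags)
  fp_pat <- sum(labels == "RS-NP" & flags)
  fp_hc <- sum(labels == "HC" & flags)
  data.frame(
    rule = rule,
    n_rsp = n_rsp, fn_count = fn,
    fn_rate = round_half_up(100 * fn / max(n_rsp, 1)),
    n_rsnp = n_rsnp, fp_patient_count = fp_pat,
    fp_patient_rate = round_half_up(100 * fp_pat / max(n_rsnp, 1)),
    n_hc = n_hc, fp_hc_count = fp_hc,
    fp_hc_rate = round_half_up(100 * fp_hc / max(n_hc, 1)),
    accuracy = round_half_up(100 * (n_rsp + n_rsnp - fn - fp_pat) /
                               max(n_rsp + n_rsnp, 1)),
    stringsAsFactors = FALSE)
}

#' Full five-rule evaluation table
#'
#' The machine twin of a published FN/FP/accuracy table: one row per rule
#' (single metrics, OR, AND, fixed 5-um) with FN rate over progressors,
#' FP rates over stable patients and healthy controls, and patient
#' accuracy.
#'
#' @inheritParams confusion
#' @param rules Rules to tabulate.
#' @return Data frame, one row per rule (columns as in [confusion()]).
#' @export
table1 <- function(calls, labels,
                   rules = c("ONH", "MAC", "OR", "AND", "FIXED5")) {
  do.call(rbind, lapply(rules, function(r) confusion(calls, labels, r)))
}

#' Format an evaluation table in the "48.4% (15)" style
#'
#' @param tab A [table1()] result.
#' @return Character matrix (rows: FN, FP patients, accuracy, FP HC).
#' @export
format_table1 <- function(tab) {
  cell <- function(rate, count) sprintf("%.1f%% (%d)", rate, count)
  out <- rbind(
    cell(tab$fn_rate, tab$fn_count),
    cell(tab$fp_patient_rate, tab$fp_patient_count),
    cell(tab$accuracy, tab$fn_count + tab$fp_patient_count),
    cell(tab$fp_hc_rate, tab$fp_hc_count))
  dimnames(out) <- list(
    c(sprintf("FN (n = %d)", tab$n_rsp[1]),
      sprintf("FP (n = %d)", tab$n_rsnp[1]),
      sprintf("Accuracy (n = %d)", tab$n_rsp[1] + tab$n_rsnp[1]),
      sprintf("FP (n = %d HC)", tab$n_hc[1])),
    tab$rule)
  out
}

#' Built-in per-eye fixture of the published counts
#'
#' Reconstructs a per-eye flag table consistent with the published
#' stratum-level counts: of 31 progressing patients, 11 were detected by
#' both metrics, 5 only by G_ONH, 11 only by G_mac and 4 by neither; of
#' 45 stable patients, 8 were flagged on G_ONH and 3 on G_mac with 1 on
#' both; of 28 healthy controls, 2 were flagged on G_ONH and 6 on G_mac
#' with 1 on both. The fixed 5-um rule flagged 10 of the 31 progressors,
#' 4 of the 45 stable patients and none of the controls (nested within
#' the G_ONH flags, which only the marginal counts constrain).
#'
#' Note one internal inconsistency of the published table: its AND-rule
#' healthy-control entry (2 eyes) contradicts both the published text and
#' the table's own OR entry, which require exactly 1 eye flagged by both
#' metrics; this fixture follows the text.
#'
#' @return Data frame: `eye_id`, `label`, `flag_onh`, `flag_mac`,
#'   `flag_or`, `flag_and`, `flag_5um`.
#' @export
paper_fixture <- function() {
  stratum <- function(label, prefix, n, onh, mac, both, five) {
    onh_only <- onh - both; mac_only <- mac - both
    none <- n - onh_only - mac_only - both
    fo <- c(rep(TRUE, both), rep(TRUE, onh_only), rep(FALSE, mac_only),
            rep(FALSE, none))
    fm <- c(rep(TRUE, both), rep(FALSE, onh_only), rep(TRUE, mac_only),
            rep(FALSE, none))
    # fixed-rule flags nested within the G_ONH-flagged eyes
    f5 <- seq_len(n) <= five
    data.frame(eye_id = sprintf("%s%03d", prefix, seq_len(n)), label = label,
               flag_onh = fo, flag_mac = fm, flag_5um = f5,
               stringsAsFactors = FALSE)
  }
  fx <- rbind(
    stratum("RS-P", "P", 31, onh = 16, mac = 22, both = 11, five = 10),
    stratum("RS-NP", "N", 45, onh = 8, mac = 3, both = 1, five = 4),
    stratum("HC", "H", 28, onh = 2, mac = 6, both = 1, five = 0))
  fx$flag_or <- fx$flag_onh | fx$flag_mac
  fx$flag_and <- fx$flag_onh & fx$flag_mac
  fx[, c("eye_id", "label", "flag_onh", "flag_mac", "flag_or", "flag_and",
         "flag_5um")]
}
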