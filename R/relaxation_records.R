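#' Per-residue 15N relaxation records
#'
#' Builds the table consumed by the relaxation module: one row per residue
#' with longitudinal and transverse autorelaxation rates, the steady-state
#' heteronuclear NOE, and optionally the transverse/longitudinal CSA/DD
#' cross-correlated cross-relaxation rates eta_xy and eta_zz.  Missing
#' errors default to 2% of the value (the typical accuracy of the
#' exponential relaxation fits); the policy is recorded in the
#' `"error_policy"` attribute.
#'
#' @param residue_seq integer vector of residue numbers.
#' @param R1,R2 rates in 1/s; must satisfy `R1 > 0`, `R2 >= R1` (ns-regime
#'   tumbling).
#' @param NOE dimensionless heteronuclear NOE.
#' @param field_MHz proton Larmor frequency in MHz (single field).
#' @param temperature_K sample temperature.
#' @param residue_code optional three-letter codes.
#' @param R1_err,R2_err,NOE_err optional 1-sigma errors.
#' @param eta_xy,eta_zz,eta_xy_err,eta_zz_err optional cross-correlated rates.
#' @return data.frame of class `"relaxation_records"`.
#' @export
relaxation_records <- function(residue_seq, R1, R2, NOE, field_MHz,
                               temperature_K = 300,
                               residue_code = NULL,
                               R1_err = NULL, R2_err = NULL, NOE_err = NULL,
                               eta_xy = NULL, eta_zz = NULL,
                               eta_xy_err = NULL, eta_zz_err = NULL) {
  n <- length(residue_seq)
  stopifnot(length(R1) == n, length(R2) == n, length(NOE) == n,
            is.numeric(field_MHz), field_MHz > 0)
  if (any(R1 <= 0) || any(R2 <= 0)) stop("R1 and R2 must be positive")
  if (any(R2 < R1)) stop("R2 < R1 is unphysical for ns-regime tumbling")
  pol <- character(0)
  if (is.null(R1_err)) { R1_err <- 0.02 * R1; pol <- c(pol, "R1_err=2%") }
  if (is.null(R2_err)) { R2_err <- 0.02 * R2; pol <- c(pol, "R2_err=2%") }
  if (is.null(NOE_err)) { NOE_err <- 0.02 * abs(NOE); pol <- c(pol, "NOE_err=2%") }
  df <- data.frame(
    residue_seq = as.integer(residue_seq),
    residue_code = if (is.null(residue_code)) "UNK" else aa_three(residue_code),
    R1 = R1, R1_err = R1_err, R2 = R2, R2_err = R2_err,
    NOE = NOE, NOE_err = NOE_err,
    eta_xy = if (is.null(eta_xy)) NA_real_ else eta_xy,
    eta_xy_err = if (is.null(eta_xy_err)) NA_real_ else eta_xy_err,
    eta_zz = if (is.null(eta_zz)) NA_real_ else eta_zz,
    eta_zz_err = if (is.null(eta_zz_err)) NA_real_ else eta_zz_err,
    stringsAsFactors = FALSE)
  attr(df, "field_MHz") <- field_MHz
  attr(df, "temperature_K") <- temperature_K
  attr(df, "error_policy") <- pol
  class(df) <- c("relaxation_records", "data.frame")
  df
}

#' Read a relaxation-rate table
#'
#' Tab/space separated columns `residue R1 R1err R2 R2err NOE NOEerr`
#' with optional `eta_xy eta_xy_err eta_zz eta_zz_err`; `#` comments
#' allowed.  The residue column accepts `12` or `HIS12`.
#'
#' @param path file path.
#' @param field_MHz proton Larmor frequency of the dataset.
#' @param temperature_K sample temperature.
#' @return a [relaxation_records()] table.
#' @export
read_relaxation_table <- function(path, field_MHz, temperature_K = 300) {
  raw <- utils::read.table(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  res <- as.character(raw[[1]])
  m <- regexec("^([A-Za-z]{3})?(\\d+)$", res)
  parts <- regmatches(res, m)
  bad <- lengths(parts) == 0
  if (any(bad)) stop("unparseable residue labels: ", paste(res[bad], collapse = ", "))
  seqs <- vapply(parts, function(p) as.integer(p[3]), integer(1))
  codes <- vapply(parts, function(p) if (nzchar(p[2])) p[2] else "UNK", character(1))
  gc <- function(nm) if (nm %in% names(raw)) raw[[nm]] else NULL
  relaxation_records(seqs, raw$R1, raw$R2, raw$NOE, field_MHz, temperature_K,
                     residue_code = codes,
                     R1_err = gc("R1err") %||% gc("R1_err"),
                     R2_err = gc("R2err") %||% gc("R2_err"),
                     NOE_err = gc("NOEerr") %||% gc("NOE_err"),
                     eta_xy = gc("eta_xy"), eta_xy_err = gc("eta_xy_err"),
                     eta_zz = gc("eta_zz"), eta_zz_err = gc("eta_zz_err"))
}

#' Write a relaxation-rate table
#' @param records a [relaxation_records()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_relaxation_table <- function(records, path) {
  df <- as.data.frame(records)
  lab <- sprintf("%s%d", df$residue_code, df$residue_seq)
  cols <- c("R1", "R1_err", "R2", "R2_err", "NOE", "NOE_err",
            "eta_xy", "eta_xy_err", "eta_zz", "eta_zz_err")
  body <- c(paste(c("residue", cols), collapse = "\t"),
            vapply(seq_len(nrow(df)), function(i)
              paste(c(lab[i], fmt_num(unlist(df[i, cols]))), collapse = "\t"),
              character(1)))
  writeLines(c(provenance_header(body),
               sprintf("# field_MHz=%s temperature_K=%s",
                       fmt_num(attr(records, "field_MHz")),
                       fmt_num(attr(records, "temperature_K"))),
               body), path)
  invisible(path)
}

#' Diamagnetic/paramagnetic peak-volume pairs
#'
#' @param residue_seq integer residue numbers.
#' @param V_dia,V_para peak volumes in the diamagnetic and paramagnetic
#'   spectrum (arbitrary, possibly different, units); `V_dia > 0`,
#'   `V_para >= 0`.
#' @param residue_code optional three-letter codes.
#' @return data.frame of class `"volume_pairs"`.
#' @export
volume_pairs <- function(residue_seq, V_dia, V_para, residue_code = NULL) {
  n <- length(residue_seq)
  stopifnot(length(V_dia) == n, length(V_para) == n)
  if (any(V_dia <= 0)) stop("V_dia must be positive")
  if (any(V_para < 0)) stop("V_para must be non-negative")
  df <- data.frame(residue_seq = as.integer(residue_seq),
                   residue_code = if (is.null(residue_code)) "UNK"
                                  else aa_three(residue_code),
                   V_dia = V_dia, V_para = V_para, stringsAsFactors = FALSE)
  class(df) <- c("volume_pairs", "data.frame")
  df
}
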