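# Cross-experiment assembly: per-residue dossier join, protection classes,
# consensus flags, and structure-mappable outputs.

#' Protection classes from protection factors
#'
#' Three-way classification of protection factors with the conventional
#' colour-map bounds: `"high"` for `P > upper`, `"mid"` for
#' `lower <= P <= upper`, `"low"` for `P < lower` (defaults 1e4 and 1e5).
#' The boundary convention is closed on the lower bound of each class.
#'
#' @param P numeric vector of protection factors (NA allowed).
#' @param bounds length-2 numeric `(lower, upper)`.
#' @return character vector `"low"`/`"mid"`/`"high"` (NA propagated).
#' @export
protection_classes <- function(P, bounds = c(1e4, 1e5)) {
  stopifnot(length(bounds) == 2L, bounds[1] < bounds[2])
  out <- rep(NA_character_, length(P))
  out[P < bounds[1]] <- "low"
  out[P >= bounds[1] & P <= bounds[2]] <- "mid"
  out[P > bounds[2]] <- "high"
  out
}

#' Join per-residue results across experiments
#'
#' Outer join keyed by residue number over whatever subset of analyses is
#' supplied; the output residue set is exactly the union of the input
#' residue sets (rows are never invented).  Consensus flags are derived
#' from configurable thresholds: `flexible` (S2 below `s2_flexible`),
#' `protected` (P above `p_protected`), `hotspot` (A above `a_hotspot`),
#' `exchange_affected` (flag from [detect_exchange()]); a flag is only
#' ever set when its supporting datum is present.
#'
#' @param hx [hx_pipeline()] results (optional).
#' @param mf a `model_free_result` (optional).
#' @param denat [aggregate_midpoints()] result (optional).
#' @param para an [attenuation()] profile (optional).
#' @param rex [detect_exchange()] result (optional).
#' @param rmsf_tab per-residue RMSF summary with `residue_seq`, `rmsf`
#'   (optional).
#' @param depth_tab per-residue depth summary with `residue_seq`, `depth`
#'   (optional).
#' @param thresholds named list overriding `s2_flexible` (0.8),
#'   `p_protected` (1e4), `a_hotspot` (1.7).
#' @return data.frame of class `"residue_dossier"`.
#' @export
residue_dossier <- function(hx = NULL, mf = NULL, denat = NULL, para = NULL,
                            rex = NULL, rmsf_tab = NULL, depth_tab = NULL,
                            thresholds = list()) {
  th <- utils::modifyList(list(s2_flexible = 0.8, p_protected = 1e4,
                               a_hotspot = 1.7), thresholds)
  pieces <- list()
  if (!is.null(hx))
    pieces$hx <- data.frame(residue_seq = hx$residue_seq, P = hx$P,
                            dG_op = hx$dG_op, k_obs = hx$k_obs)
  if (!is.null(mf))
    pieces$mf <- data.frame(residue_seq = mf$residues$residue_seq,
                            S2 = mf$residues$S2,
                            tau_e_ps = mf$residues$tau_e_ps)
  if (!is.null(denat))
    pieces$denat <- data.frame(residue_seq = denat$table$residue_seq,
                               C_half = denat$table$C_half)
  if (!is.null(para))
    pieces$para <- data.frame(residue_seq = para$residue_seq, A = para$A)
  if (!is.null(rex))
    pieces$rex <- data.frame(residue_seq = rex$residue_seq,
                             exchange_flag = rex$flagged)
  if (!is.null(rmsf_tab)) {
    agg <- stats::aggregate(rmsf ~ residue_seq, data = rmsf_tab, FUN = mean)
    pieces$rmsf <- agg
  }
  if (!is.null(depth_tab)) {
    agg <- stats::aggregate(depth ~ residue_seq, data = depth_tab, FUN = mean)
    pieces$depth <- agg
  }
  if (!length(pieces)) stop("no inputs supplied")
  out <- Reduce(function(a, b) merge(a, b, by = "residue_seq", all = TRUE),
                pieces)
  out <- out[order(out$residue_seq), , drop = FALSE]
  rownames(out) <- NULL
  flag <- function(cond) !is.na(cond) & cond
  out$flag_flexible <- if ("S2" %in% names(out))
    flag(out$S2 < th$s2_flexible) else FALSE
  out$flag_protected <- if ("P" %in% names(out))
    flag(out$P > th$p_protected) else FALSE
  out$flag_hotspot <- if ("A" %in% names(out))
    flag(out$A > th$a_hotspot) else FALSE
  out$flag_exchange <- if ("exchange_flag" %in% names(out))
    flag(out$exchange_flag) else FALSE
  if ("P" %in% names(out)) out$protection_class <- protection_classes(out$P)
  class(out) <- c("residue_dossier", "data.frame")
  out
}

#' Write per-residue annotations onto a structure
#'
#' Maps one scalar dossier column onto the B-factor column of a PDB copy
#' of the structure (residues without a datum receive the neutral value 0
#' and are listed in a mask) and writes a flat TSV of the full dossier.
#'
#' @param dossier a [residue_dossier()].
#' @param model a [structure_model()].
#' @param pdb_path,tsv_path output paths (NULL skips either output).
#' @param column dossier column mapped to the B-factor.
#' @return list with `unmapped` (structure residues without dossier rows),
#'   `masked` (dossier rows without the datum), invisibly.
#' @export
write_structure_annotation <- function(dossier, model, pdb_path = NULL,
                                       tsv_path = NULL, column = "P") {
  stopifnot(inherits(dossier, "residue_dossier"),
            inherits(model, "structure_model"))
  res_struct <- unique(model$atoms$res_seq)
  unmapped <- setdiff(res_struct, dossier$residue_seq)
  vals <- rep(0, nrow(model$atoms))
  masked <- integer(0)
  if (!is.null(pdb_path)) {
    if (!column %in% names(dossier)) stop("no dossier column ", column)
    v <- dossier[[column]][match(model$atoms$res_seq, dossier$residue_seq)]
    masked <- unique(model$atoms$res_seq[is.na(v) &
                                           model$atoms$res_seq %in% dossier$residue_seq])
    v[is.na(v)] <- 0
    # B-factor field is 6.2F; rescale magnitudes that cannot be printed
    if (max(abs(v)) >= 1000) v <- v / 10^ceiling(log10(max(abs(v)) / 999))
    write_structure(model, pdb_path, bfactor = v)
  }
  if (!is.null(tsv_path)) {
    df <- as.data.frame(dossier)
    body <- c(paste(names(df), collapse = "\t"),
              vapply(seq_len(nrow(df)), function(i)
                paste(vapply(df[i, ], function(x)
                  if (is.numeric(x)) fmt_num(x) else as.character(x),
                  character(1)), collapse = "\t"), character(1)))
    writeLines(c(provenance_header(body), body), tsv_path)
  }
  invisible(list(unmapped = unmapped, masked = masked))
}

#' JSON summary of global scalars
#'
#' @param path output path.
#' @param ... named scalars (e.g. `tau_c_ns`, `mean_S2`, `mean_C_half`,
#'   `hotspots`).
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(path, ...) {
  jsonlite::write_json(list(...), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
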