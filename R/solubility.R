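# Structure-guided solubility engineering: flag exposed hydrophobic residues
# outside the CDR loops and suggest substitutions (Ile/Leu/Val -> Ala,
# Met/Phe/Trp -> Lys by default).

HYDROPHOBIC_DEFAULT <- c("I", "L", "V", "M", "F", "W")
# informal exposure-propensity ranking used only for reporting (1 = most
# hydrophobic); Ala/Cys/Tyr deliberately excluded from the default set
HYDROPHOBICITY_RANK <- c(I = 1L, V = 2L, L = 3L, F = 4L, M = 5L, W = 6L)

#' Flag exposed hydrophobic residues outside the CDRs
#'
#' Candidates are residues of `chain` whose one-letter type belongs to
#' `hydrophobic_set`, whose relative SASA reaches `rel_sasa_min`, and whose
#' position lies outside all three CDR spans (annotation mapped positionally
#' onto the chain).  Burial is judged purely by the relative-SASA threshold:
#' exposed implies "not contributing to the hydrophobic core".
#'
#' @param model a `structure_model`.
#' @param chain antibody chain id.
#' @param annotation an `antibody_annotation` for that chain.
#' @param rel_sasa_min exposure threshold on relative SASA (default 0.30, a
#'   conventional midpoint; stated in the output header attribute).
#' @param hydrophobic_set one-letter residue types considered hydrophobic.
#' @param sasa_profile optional precomputed [sasa()] profile of `model`.
#' @return data.frame (chain, resnum, wt, rel_sasa, seq_index) sorted by
#'   decreasing relative SASA, class `solubility_candidates`.
#' @export
flag_exposed_hydrophobics <- function(model, chain, annotation,
                                      rel_sasa_min = 0.30,
                                      hydrophobic_set = HYDROPHOBIC_DEFAULT,
                                      sasa_profile = NULL) {
  stopifnot(inherits(model, "structure_model"))
  if (!chain %in% model$chain) stopf("chain %s absent from the model", chain)
  prof <- sasa_profile %||% sasa(model)
  prof <- prof[prof$chain == chain, , drop = FALSE]
  nres <- nrow(prof)
  if (max(annotation$cdr3[2L], annotation$cdr2[2L], annotation$cdr1[2L]) > nres)
    stopf("annotation does not fit the %d-residue chain %s", nres, chain)
  wt <- aa3to1(prof$resname)
  in_cdr <- (seq_len(nres) - 1L) %in% cdr_indices(annotation)
  sel <- wt %in% hydrophobic_set & !in_cdr &
    !is.na(prof$rel_sasa) & prof$rel_sasa >= rel_sasa_min
  out <- data.frame(chain = rep(chain, sum(sel)),
                    resnum = prof$resnum[sel],
                    wt = wt[sel],
                    rel_sasa = prof$rel_sasa[sel],
                    seq_index = which(sel) - 1L,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$rel_sasa), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("solubility_candidates", "data.frame"),
            rel_sasa_min = rel_sasa_min, hydrophobic_set = hydrophobic_set)
}

#' Suggest solubilising point mutations
#'
#' Default rule: branched aliphatics (I, L, V) to Ala; bulky
#' hydrophobics/aromatics (M, F, W) to Lys - the I15A / M75K pattern.  Each
#' suggestion carries its numeric evidence.
#'
#' @param candidates output of [flag_exposed_hydrophobics()].
#' @param rules named character vector mapping wild-type to proposed residue.
#' @return data.frame (chain, resnum, wt, proposed, rel_sasa,
#'   hydrophobicity_rank, reason), class `mutation_suggestions`.
#' @export
suggest_mutations <- function(candidates,
                              rules = c(I = "A", L = "A", V = "A",
                                        M = "K", F = "K", W = "K")) {
  if (!nrow(candidates)) {
    out <- data.frame(chain = character(0), resnum = integer(0),
                      wt = character(0), proposed = character(0),
                      rel_sasa = numeric(0), hydrophobicity_rank = integer(0),
                      reason = character(0), stringsAsFactors = FALSE)
    return(structure(out, class = c("mutation_suggestions", "data.frame")))
  }
  proposed <- unname(rules[candidates$wt])
  if (anyNA(proposed))
    stopf("no mutation rule for residue type(s): %s",
          paste(unique(candidates$wt[is.na(proposed)]), collapse = ", "))
  thr <- attr(candidates, "rel_sasa_min") %||% NA_real_
  out <- data.frame(
    chain = candidates$chain,
    resnum = candidates$resnum,
    wt = candidates$wt,
    proposed = proposed,
    rel_sasa = candidates$rel_sasa,
    hydrophobicity_rank = unname(HYDROPHOBICITY_RANK[candidates$wt]),
    reason = sprintf("exposed hydrophobic outside CDRs (relSASA %.2f >= %.2f)",
                     candidates$rel_sasa, thr),
    stringsAsFactors = FALSE)
  structure(out, class = c("mutation_suggestions", "data.frame"),
            rel_sasa_min = thr)
}
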