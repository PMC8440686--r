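## Inheritance-aware segregation. A verdict never filters by itself in the
## default preset — it annotates the candidate row for human review.
##
## Missing-genotype semantics: a missing call is "unknown", never
## homozygous-reference. Consequences: an uncalled index is always
## inconsistent; a parent present in the pedigree but uncalled at the site
## cannot confirm de novo status (AD-denovo fails with that reason); for all
## other models an uncalled relative is simply non-constraining. A case with
## no genotyped relatives at all (singletons) is unconstrained: every model
## returns consistent with that reason, so singleton candidates are carried
## forward without segregation evidence.

SEGREGATION_MODELS <- c("AD-denovo", "AD-inherited", "AR-hom", "XL", "MT",
                        "mosaic-candidate")

#' Segregation analysis of one variant against a family
#'
#' Model rules (for genotyped members):
#' * `AD-denovo` — index heterozygous; both parents genotyped hom-ref.
#' * `AD-inherited` — index heterozygous; at least one affected relative
#'   carries the alt; no unaffected relative carries it (unless
#'   `allow_reduced_penetrance`).
#' * `AR-hom` — index homozygous alt; every genotyped parent heterozygous.
#' * `XL` — variant on X; male index hemizygous alt with mother het or
#'   hom-ref (de novo), female index homozygous alt; an unaffected genotyped
#'   father carrying the alt is inconsistent.
#' * `MT` — variant on MT; index carries the alt.
#' * `mosaic-candidate` — index carries the alt with allelic fraction below
#'   `mosaic_af_bound`; a reporting flag, never a filter.
#'
#' @param genotypes named integer vector of alt dosages for family members
#'   (`NA` = uncalled)
#' @param ploidy named integer vector of matching ploidies
#' @param pedigree a [FamilyPedigree-class]
#' @param model one of `r paste(SEGREGATION_MODELS, collapse = ", ")`
#' @param contig contig of the variant (required by the XL and MT rules)
#' @param afrac_index index-case allelic fraction (`NA` when unavailable)
#' @param allow_reduced_penetrance tolerate unaffected het carriers under
#'   dominant models
#' @param mosaic_af_bound allelic-fraction bound for the mosaic flag
#' @return list with elements `model`, `consistent` (logical), `reason`
#' @export
segregate <- function(genotypes, ploidy, pedigree, model, contig = NA_character_,
                      afrac_index = NA_real_, allow_reduced_penetrance = FALSE,
                      mosaic_af_bound = 0.30) {
  if (!model %in% SEGREGATION_MODELS) {
    stop("unknown segregation model: ", model, call. = FALSE)
  }
  verdict <- function(ok, reason) list(model = model, consistent = ok, reason = reason)

  m <- pedMembers(pedigree)
  idx <- indexId(pedigree)
  gIdx <- genotypes[[idx]]
  pIdx <- ploidy[[idx]] %||% 2L
  if (is.null(gIdx) || is.na(gIdx)) return(verdict(FALSE, "index genotype missing"))

  relIds <- setdiff(m$experiment_id, idx)
  genotyped <- relIds[vapply(relIds, function(r) {
    !is.null(genotypes[[r]]) && !is.na(genotypes[[r]])
  }, logical(1))]
  if (!length(genotyped) && model != "mosaic-candidate" &&
      !(model %in% c("XL", "MT"))) {
    # unconstrained families: only the index genotype itself can gate
    gate <- switch(model,
      "AD-denovo" = gIdx == 1L && pIdx == 2L,
      "AD-inherited" = gIdx == 1L && pIdx == 2L,
      "AR-hom" = gIdx == pIdx && pIdx == 2L,
      TRUE)
    if (!gate) return(verdict(FALSE, "index genotype incompatible with model"))
    return(verdict(TRUE, "no relatives - unconstrained"))
  }

  idxRow <- m[m$is_index, , drop = FALSE]
  fid <- idxRow$father_id
  mid <- idxRow$mother_id
  gOf <- function(id) if (is.na(id) || is.null(genotypes[[id]])) NA_integer_ else genotypes[[id]]
  gF <- gOf(fid)
  gM <- gOf(mid)

  if (model == "AD-denovo") {
    if (!(gIdx == 1L && pIdx == 2L)) return(verdict(FALSE, "index not heterozygous"))
    if (is.na(fid) && is.na(mid)) return(verdict(TRUE, "no relatives - unconstrained"))
    for (g in c(gF, gM)[!is.na(c(gF, gM))]) {
      if (g > 0L) return(verdict(FALSE, "alt allele present in a parent"))
    }
    if ((!is.na(fid) && is.na(gF)) || (!is.na(mid) && is.na(gM))) {
      return(verdict(FALSE, "parent genotype missing - de novo unconfirmed"))
    }
    return(verdict(TRUE, "de novo: both parents hom-ref"))
  }

  if (model == "AD-inherited") {
    if (!(gIdx == 1L && pIdx == 2L)) return(verdict(FALSE, "index not heterozygous"))
    if (!length(genotyped)) return(verdict(TRUE, "no relatives - unconstrained"))
    affRel <- genotyped[m$affected[match(genotyped, m$experiment_id)]]
    unaffRel <- setdiff(genotyped, affRel)
    carriersUnaff <- unaffRel[vapply(unaffRel, function(r) genotypes[[r]] > 0L, logical(1))]
    if (length(carriersUnaff) && !allow_reduced_penetrance) {
      return(verdict(FALSE, "alt allele in unaffected relative"))
    }
    carriersAff <- affRel[vapply(affRel, function(r) genotypes[[r]] > 0L, logical(1))]
    if (!length(carriersAff)) {
      if (allow_reduced_penetrance && length(carriersUnaff)) {
        return(verdict(TRUE, "inherited from unaffected carrier (reduced penetrance)"))
      }
      return(verdict(FALSE, "no affected relative carries the alt allele"))
    }
    return(verdict(TRUE, "co-segregates with affected relative(s)"))
  }

  if (model == "AR-hom") {
    if (!(pIdx == 2L && gIdx == 2L)) return(verdict(FALSE, "index not homozygous alt"))
    for (g in c(father = gF, mother = gM)) {
      if (!is.na(g) && g != 1L) {
        return(verdict(FALSE, "genotyped parent is not heterozygous"))
      }
    }
    if (all(is.na(c(gF, gM)))) return(verdict(TRUE, "no relatives - unconstrained"))
    return(verdict(TRUE, "homozygous alt with heterozygous parent(s)"))
  }

  if (model == "XL") {
    if (is.na(contig) || normalizeContig(contig) != "X") {
      return(verdict(FALSE, "variant not on X"))
    }
    sexIdx <- idxRow$sex
    if (sexIdx == "male") {
      if (!(pIdx == 1L && gIdx == 1L)) return(verdict(FALSE, "male index not hemizygous alt"))
      if (!is.na(gM) && gM == 2L) return(verdict(FALSE, "mother homozygous alt but unaffected"))
      if (!is.na(gF) && gF > 0L && !m$affected[match(fid, m$experiment_id)]) {
        return(verdict(FALSE, "unaffected father carries the alt allele"))
      }
      reason <- if (!is.na(gM) && gM == 1L) "hemizygous alt, carrier mother"
                else if (!is.na(gM)) "hemizygous alt, de novo (mother hom-ref)"
                else "hemizygous alt, mother not genotyped"
      return(verdict(TRUE, reason))
    }
    if (sexIdx == "female") {
      if (gIdx == pIdx && pIdx == 2L) return(verdict(TRUE, "female index homozygous alt"))
      return(verdict(FALSE, "female index not homozygous alt"))
    }
    return(verdict(FALSE, "index sex unknown - X-linked model unevaluable"))
  }

  if (model == "MT") {
    if (is.na(contig) || normalizeContig(contig) != "MT") {
      return(verdict(FALSE, "variant not on MT"))
    }
    if (gIdx >= 1L) return(verdict(TRUE, "index carries mitochondrial alt"))
    return(verdict(FALSE, "index does not carry the alt allele"))
  }

  # mosaic-candidate
  if (gIdx < 1L) return(verdict(FALSE, "index does not carry the alt allele"))
  if (is.na(afrac_index)) return(verdict(FALSE, "no allelic fraction available"))
  if (afrac_index < mosaic_af_bound) {
    return(verdict(TRUE, sprintf("allelic fraction %.3f below mosaic bound %.2f",
                                 afrac_index, mosaic_af_bound)))
  }
  verdict(FALSE, "allelic fraction not in mosaic range")
}

#' Pair heterozygous variants of one gene into compound-heterozygote candidates
#'
#' With both parents genotyped, a pair qualifies when one variant is
#' paternal-only and the other maternal-only (trans configuration inferred
#' from parental origin); variants carried by both parents cannot anchor a
#' phase-known pair. Without both parents, every unordered pair of index-het
#' variants is returned flagged `phase = "unknown"`.
#'
#' @param geneVariants data.frame with one row per index-het variant in one
#'   gene: columns `key`, `g_index`, `g_father`, `g_mother` (dosages, `NA`
#'   when unavailable)
#' @param pedigree a [FamilyPedigree-class]
#' @return data.frame with columns `key1`, `key2`, `phase`
#'   (`trans` / `unknown`); zero rows when no pair qualifies
#' @export
compoundHetPairs <- function(geneVariants, pedigree) {
  empty <- data.frame(key1 = character(), key2 = character(),
                      phase = character(), stringsAsFactors = FALSE)
  hets <- geneVariants[!is.na(geneVariants$g_index) & geneVariants$g_index == 1L, ,
                       drop = FALSE]
  k <- nrow(hets)
  if (k < 2L) return(empty)
  bothParents <- all(!is.na(hets$g_father)) && all(!is.na(hets$g_mother))
  if (!bothParents) {
    combs <- utils::combn(hets$key, 2L)
    return(data.frame(key1 = combs[1, ], key2 = combs[2, ],
                      phase = "unknown", stringsAsFactors = FALSE))
  }
  paternal <- hets$g_father >= 1L & hets$g_mother == 0L
  maternal <- hets$g_mother >= 1L & hets$g_father == 0L
  pairs <- empty
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      trans <- (paternal[i] && maternal[j]) || (maternal[i] && paternal[j])
      if (trans) {
        pairs <- rbind(pairs, data.frame(key1 = hets$key[i], key2 = hets$key[j],
                                         phase = "trans", stringsAsFactors = FALSE))
      }
    }
  }
  pairs
}
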