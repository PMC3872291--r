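#' Reference table of NH2-terminal phosphorylation sites
#'
#' The five phospho-sites mapped in the Pro/Ala rich region and the M-motif,
#' in both species numberings: mouse Ser-59/Ser-62 (PKA) and Ser-83/Thr-84
#' (PKC) in the Pro/Ala region, and Ser-204 (PKA and PKC) in the M-motif.
#' Mouse Ser-59, Ser-83 and Ser-204 correspond to human Ser-61, Ser-85 and
#' Ser-206; mouse Ser-62 aligns with human Thr-64; mouse Thr-84 has no human
#' counterpart. Human sites are predictions by homology - human sMyBP-C
#' phosphorylation has not been assayed directly.
#'
#' @return A tibble with columns `species`, `site`, `kinase`, `region` and
#'   `rule` (`exon5` for the site inside the spliced exon-5 segment,
#'   `exon10` for the M-motif site, `proala` for the constitutive Pro/Ala
#'   sites, which survive only if the Pro/Ala region itself is translated).
#' @examples
#' phospho_sites()
#' @export
phospho_sites <- function() {
  tibble::tibble(
    species = c(rep("human", 4), rep("mouse", 5)),
    site   = c("S61", "T64", "S85", "S206",
               "S59", "S62", "S83", "T84", "S204"),
    kinase = c("PKA", "PKA", "PKC", "PKA+PKC",
               "PKA", "PKA", "PKC", "PKC", "PKA+PKC"),
    region = c("ProAla", "ProAla", "ProAla", "M-motif",
               "ProAla", "ProAla", "ProAla", "ProAla", "M-motif"),
    rule   = c("exon5", "proala", "proala", "exon10",
               "exon5", "proala", "proala", "proala", "exon10")
  )
}

#' Annotate predicted phosphorylation sites
#'
#' Applies the exon-presence rules to each variant: the constitutive Pro/Ala
#' sites (human Thr-64/Ser-85; mouse Ser-62/Ser-83/Thr-84) are present iff
#' the Pro/Ala region itself is translated (it is lost to the internal start
#' of h-v012); the exon-5 site (human Ser-61 / mouse Ser-59) additionally
#' requires exon 5; the M-motif site (human Ser-206 / mouse Ser-204) requires
#' exon 10 and is therefore absent only in h-v8. Sites are reported in the
#' numbering of each variant's own species and are predictions from exon
#' composition, not assay results. Partial records are refused: their exon
#' complement is not fully known, so no presence call is defensible.
#'
#' @param variants One or more catalog rows (a catalog tibble or subset).
#' @return A long tibble with one row per variant per species-appropriate
#'   site: `id`, `site`, `kinase`, `region`, `present`.
#' @examples
#' cat <- mybpc_catalog()
#' annotate_phospho(dplyr::filter(cat, id == "h-v1"))
#' @export
annotate_phospho <- function(variants) {
  variants <- tibble::as_tibble(variants)
  if (any(variants$partial)) {
    abort(paste0(
      "cannot annotate partial variant(s) ",
      paste(variants$id[variants$partial], collapse = ", "),
      ": exon complement incomplete, phospho-site presence is undefined"
    ))
  }
  sites <- phospho_sites()
  out <- variants %>%
    dplyr::mutate(
      proala_present = is.na(.data$tss_truncation) | .data$tss_truncation <= 2L
    ) %>%
    dplyr::select("id", "species", "exon5", "exon10", "proala_present") %>%
    dplyr::inner_join(sites, by = "species", relationship = "many-to-many") %>%
    dplyr::mutate(
      present = dplyr::case_when(
        rule == "proala" ~ proala_present,
        rule == "exon5"  ~ proala_present & exon5,
        rule == "exon10" ~ exon10
      )
    ) %>%
    dplyr::select("id", "site", "kinase", "region", "present")
  out
}

#' Predict sarcomeric localization from the COOH-terminal splice state
#'
#' Variants retaining both exons 31 and 32 concentrate at the periphery of
#' the M-band; variants lacking exon 31 but keeping exon 32 target the
#' C-zone of the A-band. The two remaining terminal states (exon 31 only,
#' as in h-v5; neither exon, as in h-v10) have no reported localization and
#' are returned as `"unknown"` - never imputed.
#'
#' @param variants One or more catalog rows.
#' @return A tibble with columns `id` and `localization`
#'   (`"A-band"`, `"M-band"` or `"unknown"`).
#' @examples
#' predict_localization(mybpc_catalog())
#' @export
predict_localization <- function(variants) {
  variants <- tibble::as_tibble(variants)
  tibble::tibble(
    id = variants$id,
    localization = dplyr::case_when(
      variants$exon31 & variants$exon32  ~ "M-band",
      !variants$exon31 & variants$exon32 ~ "A-band",
      TRUE ~ "unknown"
    )
  )
}

#' Categorical actomyosin / LMM interaction profile
#'
#' NH2-terminal class by Pro/Ala exon complement: variants with all of exons
#' 2-5 bind both actin and heavy meromyosin and exert the strongest
#' modulatory effect (`strong_actin_myosin`, v1/v2); the exon 2+3 variants
#' compete with actin for the myosin head (`strong_competing`); the
#' exon-2-only NH2-terminus interacts with HMM alone and has a moderate
#' effect (`moderate_hmm_only`, v002); every other NH2-terminus (including
#' the internally initiated h-v012) is functionally uncharacterized and
#' reported `unknown`. COOH-terminal light-meromyosin binding follows the
#' exon 31/32 state: both retained gives preferential LMM binding, exon 32
#' alone gives weak binding, and the two remaining states are unknown.
#' These are categorical labels; no binding affinities are modeled.
#'
#' @param variants One or more catalog rows.
#' @return A tibble with columns `id`, `nterm_class`, `lmm_binding`.
#' @examples
#' interaction_profile(mybpc_catalog())
#' @export
interaction_profile <- function(variants) {
  variants <- tibble::as_tibble(variants)
  truncated <- !is.na(variants$tss_truncation)
  nterm <- dplyr::case_when(
    truncated ~ "unknown",
    variants$exon2 & variants$exon3 & variants$exon4 & variants$exon5 ~
      "strong_actin_myosin",
    variants$exon2 & variants$exon3 & !variants$exon4 & !variants$exon5 ~
      "strong_competing",
    variants$exon2 & !variants$exon3 & !variants$exon4 & !variants$exon5 ~
      "moderate_hmm_only",
    TRUE ~ "unknown"
  )
  lmm <- dplyr::case_when(
    variants$exon31 & variants$exon32  ~ "preferential",
    !variants$exon31 & variants$exon32 ~ "weak",
    TRUE ~ "unknown"
  )
  tibble::tibble(id = variants$id, nterm_class = nterm, lmm_binding = lmm)
}

#' Full rule-based annotation of a catalog
#'
#' Convenience wrapper joining [predict_localization()],
#' [interaction_profile()] and the per-variant count of predicted
#' phosphorylation sites onto the catalog.
#'
#' @param catalog A catalog tibble.
#' @return The catalog with `localization`, `nterm_class`, `lmm_binding` and
#'   `n_phospho_sites` columns appended.
#' @examples
#' annotate_variants(mybpc_catalog())
#' @export
annotate_variants <- function(catalog) {
  phos <- annotate_phospho(catalog) %>%
    dplyr::filter(.data$present) %>%
    dplyr::count(.data$id, name = "n_phospho_sites")
  catalog %>%
    dplyr::left_join(predict_localization(catalog), by = "id") %>%
    dplyr::left_join(interaction_profile(catalog), by = "id") %>%
    dplyr::left_join(phos, by = "id") %>%
    dplyr::mutate(n_phospho_sites = dplyr::coalesce(.data$n_phospho_sites, 0L))
}
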