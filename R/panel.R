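#' Default 87-metabolite plasma panel
#'
#' Builds the generative specification of a targeted plasma panel covering
#' acylcarnitines, tryptophan catabolites (kynurenine, serotonin and indole
#' pathways), NO/urea-cycle intermediates, proteinogenic amino acids and
#' methionine/cystathionine-cycle metabolites, 87 analytes in total.
#' Baselines are literature-typical plasma concentrations in umol/L at the
#' reference age. Age slopes (as fractions of baseline per year) are given
#' to metabolites with well-described age dependence (e.g. cystathionine,
#' citrulline, dimethylarginines, long-chain acylcarnitines, kynurenine
#' intermediates rise with age; serotonin, glycine, taurine decline).
#' Group effects are signed log2 fold changes applied to the case (IHD)
#' group for the disease-associated analytes and ratio precursors; all
#' other panel members act as null "filler" features.
#'
#' @param noise_cv coefficient of variation of the multiplicative log-normal
#'   noise, shared by all metabolites (default 0.25, a typical targeted-assay
#'   plus biological CV).
#' @return A [MetabolitePanel-class] with 87 specs.
#' @examples
#' panel <- buildDefaultPanel()
#' length(panel)
#' @export
buildDefaultPanel <- function(noise_cv = 0.25) {
  row <- function(name, class, baseline) {
    data.frame(name = name, class_label = class, baseline = baseline,
               stringsAsFactors = FALSE)
  }
  acyl <- row(c("Carnitine", "Acetylcarnitine", "Propionylcarnitine",
                "Butyrylcarnitine", "Isovalerylcarnitine", "Tiglylcarnitine",
                "Hexanoylcarnitine", "Glutarylcarnitine", "Adipoylcarnitine",
                "Octanoylcarnitine", "Decanoylcarnitine",
                "Dodecanoylcarnitine", "Tetradecanoylcarnitine",
                "Tetradecenoylcarnitine", "Hydroxytetradecanoylcarnitine",
                "Hexadecanoylcarnitine", "Hexadecenoylcarnitine",
                "Hydroxyhexadecanoylcarnitine", "Hydroxyhexadecenoylcarnitine",
                "Octadecanoylcarnitine", "Octadecenoylcarnitine",
                "Hydroxyoctadecanoylcarnitine", "Malonylcarnitine",
                "Methylmalonylcarnitine", "Hydroxybutyrylcarnitine",
                "Hydroxyisovalerylcarnitine"),
              "acylcarnitine",
              c(40, 8, 0.4, 0.25, 0.12, 0.04, 0.08, 0.06, 0.05, 0.15, 0.25,
                0.1, 0.035, 0.05, 0.01, 0.1, 0.03, 0.008, 0.006, 0.05, 0.1,
                0.005, 0.03, 0.04, 0.03, 0.04))
  trp <- row(c("Tryptophan", "Serotonin", "Kynurenine", "Kynurenic acid",
               "Anthranilic acid", "Xanthurenic acid", "3-Hydroxykynurenine",
               "Quinolinic acid", "Indole-3-propionic acid",
               "Indole-3-butyric acid", "Indole-3-carboxaldehyde",
               "Indole-3-acetic acid", "Indole-3-lactic acid", "Tryptamine",
               "5-Hydroxyindoleacetic acid", "Melatonin"),
             "tryptophan_pathway",
             c(60, 0.6, 2, 0.05, 0.08, 0.02, 0.04, 0.4, 0.8, 0.05, 0.06,
               1.2, 0.5, 0.01, 0.05, 0.001))
  nou <- row(c("Arginine", "Asymmetric dimethylarginine",
               "Symmetric dimethylarginine", "Monomethylarginine",
               "Citrulline", "Ornithine", "Homoarginine"),
             "no_urea_cycle",
             c(80, 0.5, 0.5, 0.1, 30, 60, 1.5))
  aa <- row(c("Alanine", "Asparagine", "Aspartic acid", "Glutamine",
              "Glutamate", "Glycine", "Histidine", "Isoleucine", "Leucine",
              "Lysine", "Methionine", "Phenylalanine", "Proline", "Serine",
              "Threonine", "Tyrosine", "Valine", "3-Aminoisobutyric acid",
              "Taurine", "2-Aminobutyric acid"),
            "amino_acid",
            c(350, 45, 10, 550, 50, 220, 80, 60, 120, 170, 25, 55, 180, 110,
              130, 60, 220, 2, 50, 20))
  cys <- row(c("Cystathionine", "Homocysteine", "Methionine sulfoxide",
               "Betaine", "Choline", "Dimethylglycine", "Sarcosine",
               "Norepinephrine", "Cysteine"),
             "cystathionine_cycle",
             c(0.15, 9, 1.2, 35, 9, 3, 1.3, 0.003, 250))
  oth <- row(c("Creatinine", "Trimethylamine N-oxide", "Hippuric acid",
               "Carnosine", "Putrescine", "Spermidine", "Spermine",
               "Acetylornithine", "4-Hydroxyproline"),
             "other",
             c(80, 4, 3, 0.5, 0.1, 0.15, 0.05, 0.3, 10))
  specs <- rbind(acyl, trp, nou, aa, cys, oth)

  slope_frac <- c(
    "Cystathionine" = 0.012, "Homocysteine" = 0.008, "Citrulline" = 0.008,
    "Asymmetric dimethylarginine" = 0.006,
    "Symmetric dimethylarginine" = 0.006,
    "Hydroxytetradecanoylcarnitine" = 0.008,
    "Hydroxyhexadecanoylcarnitine" = 0.008,
    "Hydroxyhexadecenoylcarnitine" = 0.008,
    "Hexadecanoylcarnitine" = 0.005, "Octadecanoylcarnitine" = 0.005,
    "Kynurenine" = 0.008, "Kynurenic acid" = 0.010,
    "Quinolinic acid" = 0.010, "Creatinine" = 0.005,
    "Carnitine" = 0.003, "Acetylcarnitine" = 0.004,
    "Serotonin" = -0.004, "Tryptophan" = -0.002, "Glycine" = -0.002,
    "Serine" = -0.002, "Threonine" = -0.002, "Taurine" = -0.003,
    "Histidine" = -0.001)
  specs$age_slope <- unname(
    ifelse(specs$name %in% names(slope_frac),
           slope_frac[specs$name] * specs$baseline, 0))

  # Signed log2 effects calibrated so that, under the default noise CV,
  # each disease analyte's expected standalone rank AUC sits on the
  # 0.62-0.84 scale typical of published IHD panels:
  # |lfc| = sqrt(2) * qnorm(AUC) * sdlog / log(2) with sdlog at cv = 0.25.
  effects <- c(
    "Hydroxyhexadecanoylcarnitine" = 0.50,
    "Hydroxyhexadecenoylcarnitine" = 0.18,
    "Hydroxytetradecanoylcarnitine" = 0.31,
    "Adipoylcarnitine" = 0.21, "Glutarylcarnitine" = -0.26,
    "Propionylcarnitine" = -0.17, "Carnitine" = -0.34,
    "Tryptophan" = -0.17, "Serotonin" = 0.34,
    "Indole-3-propionic acid" = -0.29, "Indole-3-butyric acid" = -0.23,
    "Indole-3-carboxaldehyde" = -0.15, "Kynurenic acid" = 0.22,
    "Anthranilic acid" = 0.31, "Xanthurenic acid" = 0.15,
    "Asymmetric dimethylarginine" = -0.26, "Arginine" = -0.23,
    "Citrulline" = -0.22,
    "Isoleucine" = 0.23, "Threonine" = -0.46, "Histidine" = -0.42,
    "Phenylalanine" = 0.40, "Proline" = -0.32, "Lysine" = -0.29,
    "Glycine" = -0.23, "Leucine" = 0.19, "Aspartic acid" = -0.15,
    "Asparagine" = -0.22, "3-Aminoisobutyric acid" = 0.18,
    "Tyrosine" = -0.15,
    "Cystathionine" = 0.18, "Methionine sulfoxide" = -0.23,
    "Norepinephrine" = -0.35, "Dimethylglycine" = 0.21,
    "Valine" = 0.15, "Glutamine" = 0.10, "Serine" = -0.08,
    "Hexadecanoylcarnitine" = 0.25, "Methionine" = -0.15)
  specs$group_log2_effect <- unname(
    ifelse(specs$name %in% names(effects), effects[specs$name], 0))
  specs$noise_cv <- noise_cv
  MetabolitePanel(specs)
}

#' Short-code aliases for panel metabolites
#'
#' Maps the short acylcarnitine/amino-acid codes commonly used in
#' targeted-metabolomics reports (C0, C3, C16-OH, ADMA, ...) onto the full
#' panel names used by [buildDefaultPanel()]. Used by
#' [readConcentrationTable()] to normalize input column names.
#'
#' @return Named character vector: names are aliases, values canonical names.
#' @examples
#' metaboliteAliases()[["C16-OH"]]
#' @export
metaboliteAliases <- function() {
  c("C0" = "Carnitine", "C2" = "Acetylcarnitine",
    "C3" = "Propionylcarnitine", "C4" = "Butyrylcarnitine",
    "C5" = "Isovalerylcarnitine", "C5-DC" = "Glutarylcarnitine",
    "C6" = "Hexanoylcarnitine", "C6-DC" = "Adipoylcarnitine",
    "C8" = "Octanoylcarnitine", "C10" = "Decanoylcarnitine",
    "C12" = "Dodecanoylcarnitine", "C14" = "Tetradecanoylcarnitine",
    "C14-1" = "Tetradecenoylcarnitine",
    "C14-OH" = "Hydroxytetradecanoylcarnitine",
    "C16" = "Hexadecanoylcarnitine", "C16-1" = "Hexadecenoylcarnitine",
    "C16-OH" = "Hydroxyhexadecanoylcarnitine",
    "C16-1-OH" = "Hydroxyhexadecenoylcarnitine",
    "C18" = "Octadecanoylcarnitine", "C18-1" = "Octadecenoylcarnitine",
    "C18-OH" = "Hydroxyoctadecanoylcarnitine",
    "ADMA" = "Asymmetric dimethylarginine",
    "SDMA" = "Symmetric dimethylarginine",
    "NMMA" = "Monomethylarginine", "DMG" = "Dimethylglycine",
    "TMAO" = "Trimethylamine N-oxide",
    "5-HIAA" = "5-Hydroxyindoleacetic acid")
}
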