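# Builds inst/extdata/rxriskv_mod_2010.json, the shipped RxRiskV (mod) catalog.
# Ranges printed as "X01AA03 - X01AA07" are expanded literally within their
# chemical subgroup; the one range spanning subgroups (C01BA01-C01BD01) is
# expanded hierarchically (C01BA, C01BB, C01BC prefixes + exact C01BD01).
# Three printed literals violate the ATC grammar (NO2AX05, N0BC09, NO2BA01);
# they are stored verbatim with corrected forms alongside.
# Run from the package root: Rscript data-raw/build_catalog.R

suppressMessages(library(jsonlite))

seq2 <- function(stem, from, to) sprintf("%s%02d", stem, from:to)

cat_entry <- function(name, includes, excludes = character(),
                      all_of_groups = list(), verbatim_literals = character(),
                      corrected_codes = character(), concordant = FALSE) {
  list(name = name, includes = includes, excludes = excludes,
       all_of_groups = all_of_groups, verbatim_literals = verbatim_literals,
       corrected_codes = corrected_codes, concordant = concordant)
}

chf_loop <- c("C03CA", "C03CB", "C03CC01", "C03DA")
chf_ace  <- c(seq2("C09AA", 1, 10), "C09CA06", "C09CA07", "C09CA01", "C09CA03")

cats <- list(
  cat_entry("Alcohol dependency", c("N07BB03", "N07BB04", "N07BB01")),
  cat_entry("Allergies",
    c("R01AC", "R01AD", seq2("R06AD", 2, 9), "R06AD52", "R06AD55",
      "R06AE", "R06AK", "R06AX"),
    excludes = c("R06AX27", "R06AX28", "R06AX53", "R06AX58")),
  cat_entry("Anti-coagulation therapy",
    c("B01AA03", "B01AA04", seq2("B01AA", 7, 11), "B01AB01", "B01AB02",
      seq2("B01AB", 4, 6), "B01AB10")),
  cat_entry("Anti-platelet therapy",
    c(seq2("B01AC", 4, 19), "B01AC30", "B01AC22", "B01AC23"),
    concordant = TRUE),
  cat_entry("Anxiety", c(seq2("N05BA", 1, 12), "N05BB01")),
  cat_entry("Arrhythmia", c("C01AA05", "C01BA", "C01BB", "C01BC", "C01BD01")),
  cat_entry("Angina",
    c("C01DA02", "C01DA04", "C01DA05", seq2("C01DA", 7, 9), "C01DA13",
      "C01DA14", "C01DX16", "C01EB15", "C01EB17", "C01EB18")),
  cat_entry("Benign prostate hypertrophy", c("G04CA02", "G04CA03")),
  cat_entry("Bipolar disorder", "N05AN01"),
  cat_entry("Chronic Heart failure",
    c(chf_loop, chf_ace),
    all_of_groups = list(chf_loop, chf_ace)),
  cat_entry("Dementia", c("N06DA02", "N06DA03", "N06DA04", "N06DX")),
  cat_entry("Depression", "N06A"),
  cat_entry("End stage renal disease", c("B03XA", "V03AE02", "V03AE03", "A11CC")),
  cat_entry("Epilepsy",
    c(seq2("N03AA", 1, 4), "N03AA30", seq2("N03AB", 1, 5), "N03AB52",
      "N03AB54", "N03AC01", "N03AC02", "N03AC03", "N03AD01", "N03AD02",
      "N03AD03", "N03AD51", "N03AE01", "N03AF01", "N03AF02",
      seq2("N03AG", 1, 6), "N03AX")),
  cat_entry("Gastric-oesophageal reflux disorder & Peptic ulcer", "A02B"),
  cat_entry("Glaucoma",
    c(seq2("S01EA", 1, 5), "S01EA51", seq2("S01EB", 1, 3), "S01EC03",
      "S01EC04", seq2("S01ED", 1, 6), "S01ED51", "S01ED52", "S01ED54",
      seq2("S01EE", 1, 4), "S01EX01", "S01EX02")),
  cat_entry("Gout",
    c("M04AA01", "M04AA02", "M04AA03", "M04AA51", seq2("M04AB", 1, 4),
      "M04AC01")),
  cat_entry("Hepatitis C", "J05AB54"),
  cat_entry("HIV",
    c(seq2("J05AE", 1, 8), seq2("J05AF", 1, 11), "J05AG01", "J05AG02",
      "J05AG03", seq2("J05AR", 1, 6), "J05AX07")),
  cat_entry("Hyperkalaemia", "V03AE01"),
  cat_entry("Hyperlipidemia",
    c("C10AA", "C10AB", "C10AC", "C10AD", "C10AX", "C10BA", "C10BX"),
    concordant = TRUE),
  cat_entry("Hypertension",
    c("C03AA", "C03AB", "C03AH", "C03AX01", "C02CA04", seq2("C03BA", 2, 5),
      seq2("C03BA", 7, 11), "C03DB01", "C03DB02", "C03EA", seq2("C09BA", 2, 9),
      "C09BB", "C09DB", "C09DA02", "C09DA03", "C09DA04", "C09DA06", "C09DA07",
      "C09DA01", "C02AB01", "C02AB02", "C02AC01", "C02AC02", "C02AC04",
      "C02AC05", "C02DB02", "C02DB03", "C02DB04", "C02DC01", "C02DD01",
      "C02DG01", "C02KA01", "C02KB01", "C02KC01", "C02KD01", "C02KX01",
      "C09XA"),
    concordant = TRUE),
  cat_entry("Hypothyroidism", c("H03AA01", "H03AA02")),
  cat_entry("Heart disease",
    c("C07AA01", "C07AA02", "C07AA03", "C07AA05", "C07AA06", "C07AA07",
      "C07AA12", "C07AA14", "C07AA15", "C07AA16", "C07AA17", "C07AA19",
      "C07AA23", "C07AA27", "C07AA57", "C07AB", "C07AG01", "C07AG02",
      "C07BA02", "C07BA05", "C07BA06", "C07BA07", "C07BA12", "C07BA68",
      "C07BB02", "C07BB03", "C07BB04", "C07BB06", "C07BB07", "C07BB52",
      "C07BG01", "C07CA02", "C07CA03", "C07CA17", "C07CA23", "C07CB02",
      "C07CB03", "C07CB53", "C07CG01", "C07DA06", "C07DB01", "C07FA05",
      "C07FB02", "C07FB03", "C07FB07", seq2("C08CA", 1, 15), "C08CA55",
      "C08CX01", "C08DA01", "C08DA02", "C08DA51", "C08DB01"),
    concordant = TRUE),
  cat_entry("Inflammatory bowel disease", seq2("A07EC", 1, 4)),
  cat_entry("Liver failure", "A06AD11"),
  cat_entry("Malignancies",
    c("L01AA01", "L01AA02", "L01AA03", "L01AA05", "L01AA06", "L01AA07",
      "L01AA08", "L01AB", "L01AC", "L01AD", "L01AG01", "L01AX",
      "L01BA01", "L01BA03", "L01BA04", seq2("L01BB", 2, 7), "L01BC",
      "L01CA", "L01CB", "L01CC01", "L01CD", "L01CX01", "L01DA01",
      "L01DB", "L01DC", "L01XA", "L01XB01", "L01XC", "L01XD01",
      seq2("L01XD", 3, 6), "L01XE", "L01XX", "L02BA01", "L02BA02",
      "L02BG02", "L02BG03", "L02BG04", "L02BG06", "L02BB01", "L02BB03",
      "L02AE02", "L02AE04", "L02AB01")),
  cat_entry("Migraine",
    c("N02CA01", "N02CA02", "N02CA04", "N02CA07", "N02CA51", "N02CA52",
      "N02CA72", "N02CB01", seq2("N02CC", 1, 7), "N02CX01")),
  cat_entry("Osteoporosis",
    c("M05BA", "M05BB", "M05BX03", "G03XC01", "A12AX92")),
  cat_entry("Pain - Opiates",
    c("N02AA", "N02AB", "N02AC01", "N02AC03", "N02AC04", "N02AC05",
      "N02AC52", "N02AC54", "N02AC74", "N02AD01", "N02AD02", "N02AE01",
      "N02AF01", "N02AF02", "N02AG", "N02AX01", "N02AX02", "N02AX52"),
    verbatim_literals = "NO2AX05", corrected_codes = "N02AX05"),
  cat_entry("Pain - Anti-inflammatory agents",
    c("M01AB", "M01AC01", "M01AC02", "M01AC04", "M01AC05", "M01AC06",
      "M01AE", "M01AG", "M01AH", "N02BE51", "N02BG06"),
    verbatim_literals = "NO2BA01", corrected_codes = "N02BA01"),
  cat_entry("Pancreatic insufficiency", "A09AA02"),
  cat_entry("Parkinson's disease",
    c(seq2("N04AA", 1, 5), seq2("N04AA", 8, 12), "N04AB01", "N04AB02",
      "N04AC01", "N04AC30", seq2("N04BA", 1, 6), "N04BB01",
      seq2("N04BC", 1, 7), "N04BD01", "N04BX01", "N04BX02", "N04BD02"),
    verbatim_literals = "N0BC09", corrected_codes = "N04BC09"),
  cat_entry("Psoriasis", c("D05BB01", "D05BB02", "D05AX")),
  cat_entry("Psychotic illness",
    c("N05AA", "N05AB", "N05AC", "N05AD", "N05AE", "N05AF", "N05AG",
      "N05AH", "N05AL", "N05AN01", "N05AX")),
  cat_entry("Chronic airways disease",
    c("R03AC", "R03AK", "R03BA", "R03AB", "R03BC01", "R03BC03", "R03BX01",
      "R03CA02", "R03CB", "R03CC", "R03CC53", "R03DA", "R03DB", "R03DC",
      "R03BB")),
  cat_entry("Smoking cessation", c("N07BA01", "N07BA03")),
  cat_entry("Steroid responsive disease", c("H02AB", "H02AA")),
  cat_entry("Transplant",
    c(seq2("L04AA", 1, 6), seq2("L04AA", 8, 12), seq2("L04AA", 14, 19),
      "L04AA21", "L04AD02", "L04AX01")),
  cat_entry("Tuberculosis",
    c("J04AB04", "J04AB05", "J04AB30", "J04AC01", "J04AC51", "J04AD01",
      "J04AD02", "J04AD03", "J04AK01", "J04AK02")),
  cat_entry("Neurogenic Bladder and Urinary Incontinence", "V07AN"),
  cat_entry("Ostomy", "V07AS")
)

# Priority ranks: clinically severe / specific categories resolve first,
# symptomatic therapy classes last. Editable, deterministic stand-in for the
# unpublished "highest ranked licensed indication" ordering.
priority_order <- c(
  "Transplant", "HIV", "Malignancies", "Hepatitis C", "Tuberculosis",
  "End stage renal disease", "Liver failure", "Chronic Heart failure",
  "Arrhythmia", "Angina", "Heart disease", "Hypertension", "Hyperlipidemia",
  "Anti-coagulation therapy", "Anti-platelet therapy", "Hyperkalaemia",
  "Epilepsy", "Parkinson's disease", "Dementia", "Bipolar disorder",
  "Psychotic illness", "Depression", "Anxiety", "Alcohol dependency",
  "Smoking cessation", "Chronic airways disease", "Allergies", "Glaucoma",
  "Hypothyroidism", "Gout", "Osteoporosis", "Inflammatory bowel disease",
  "Pancreatic insufficiency",
  "Gastric-oesophageal reflux disorder & Peptic ulcer",
  "Benign prostate hypertrophy",
  "Neurogenic Bladder and Urinary Incontinence", "Ostomy", "Psoriasis",
  "Migraine", "Steroid responsive disease",
  "Pain - Anti-inflammatory agents", "Pain - Opiates"
)

names_in_file <- vapply(cats, `[[`, "", "name")
stopifnot(length(cats) == 42L, !anyDuplicated(names_in_file),
          setequal(priority_order, names_in_file),
          length(priority_order) == 42L)

for (i in seq_along(cats)) {
  cats[[i]]$priority_rank <- match(cats[[i]]$name, priority_order)
}

out <- list(version = "rxriskv_mod_2010", categories = cats)
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
writeLines(toJSON(out, auto_unbox = TRUE, pretty = TRUE),
           "inst/extdata/rxriskv_mod_2010.json")
cat("wrote inst/extdata/rxriskv_mod_2010.json:", length(cats), "categories\n")
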