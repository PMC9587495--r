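# Small synthetic terminology subsets used by the generator and the
# examples. These are hand-curated, French-oriented extracts in the shape of
# the real nomenclatures (ICD-10 diagnoses, ATC drugs, LOINC laboratory
# tests), not redistributions of the licensed releases.

#' Built-in synthetic terminology dictionaries
#'
#' Returns a small ICD-10, ATC and LOINC dictionary subset (synthetic,
#' French preferred terms with common register phrasings as synonyms),
#' enough to exercise terminology mapping end to end without any licensed
#' terminology content.
#'
#' @return named list of `term_dictionary` objects: `icd10`, `atc`, `loinc`.
#' @export
builtin_dictionaries <- function() {
  icd10 <- as_dictionary(data.frame(
    code = c("A01.0", "A09", "B05", "B54", "E11", "I10",
             "J11", "J15", "K29", "M54.5", "N39.0"),
    system = "ICD10",
    preferred_term = c(
      "Fièvre typhoïde", "Diarrhée et gastro-entérite", "Rougeole",
      "Paludisme", "Diabète de type 2", "Hypertension essentielle",
      "Grippe", "Pneumonie bactérienne", "Gastrite",
      "Lombalgie", "Infection des voies urinaires"),
    synonyms = c(
      "typhoïde", "diarrhée aiguë|gastro-entérite", "",
      "paludisme grave|palu|accès palustre", "diabète",
      "hypertension artérielle|HTA", "syndrome grippal",
      "pneumonie", "gastrite aiguë", "douleur lombaire",
      "infection urinaire"),
    stringsAsFactors = FALSE
  ))
  atc <- as_dictionary(data.frame(
    code = c("A02BC01", "C03CA01", "J01CA04", "J01EE01",
             "M01AE01", "N02BE01", "P01BF01"),
    system = "ATC",
    preferred_term = c(
      "Oméprazole", "Furosémide", "Amoxicilline",
      "Sulfaméthoxazole et triméthoprime", "Ibuprofène",
      "Paracétamol", "Artéméther et luméfantrine"),
    synonyms = c("", "", "amoxicilline sirop", "cotrimoxazole", "",
                 "paracétamol comprimé", "artéméther luméfantrine"),
    stringsAsFactors = FALSE
  ))
  loinc <- as_dictionary(data.frame(
    code = c("2160-0", "2345-7", "6690-2", "718-7", "777-3", "32700-7"),
    system = "LOINC",
    preferred_term = c(
      "Créatinine", "Glucose", "Leucocytes", "Hémoglobine",
      "Plaquettes", "Recherche de Plasmodium (goutte épaisse)"),
    synonyms = c("créatininémie", "glycémie", "numération leucocytaire",
                 "taux d'hémoglobine", "numération plaquettaire",
                 "goutte épaisse|frottis sanguin"),
    stringsAsFactors = FALSE
  ))
  list(icd10 = icd10, atc = atc, loinc = loinc)
}
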