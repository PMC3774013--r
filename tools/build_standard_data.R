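# One-time builder for the packaged 2012 WHO VA standard data files under
# inst/extdata/. Deterministic (no RNG); re-running reproduces the files byte
# for byte. The cause list and subsumption map are transcriptions of the
# published 2012 WHO VA standard; the indicator registry ships stub items whose
# per-age-group, per-skip-level and distinct counts exactly reproduce the
# published pattern (the official item texts are distributed by WHO, not
# reprinted here; the registry file is data and can be swapped for them).

suppressMessages(library(jsonlite))

out_dir <- file.path("inst", "extdata")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

## ---------------------------------------------------------------- cause list

# to_icd entries: "CODE" or "CODE|context". First entry is the default
# certification code. from_icd entries: "A00-A09" ranges, single codes, or
# subcoded codes ("O75.3").
cause <- function(va_code, title, group_code, to_icd, from_icd, notes = "",
                  is_cause = TRUE) {
  # is_cause = FALSE for VA-99 (cause of death unknown): it is a mapping
  # target and assignment fallback, but not one of the 62 cause categories
  # (60 causes + 2 stillbirths).
  list(va_code = va_code, title = title, group_code = group_code,
       to_icd = as.list(to_icd), from_icd = as.list(from_icd), notes = notes,
       is_cause = is_cause)
}

causes <- list(
  cause("VAs-01.01", "Sepsis", "VAs-01", "A41", "A40-A41"),
  cause("VAs-01.02", "Acute respiratory infection, including pneumonia",
        "VAs-01", c("J22", "J18"), "J00-J22"),
  cause("VAs-01.03", "HIV/AIDS related death", "VAs-01", "B24", "B20-B24"),
  cause("VAs-01.04", "Diarrhoeal diseases", "VAs-01", "A09", "A00-A09"),
  cause("VAs-01.05", "Malaria", "VAs-01", "B54", "B50-B54"),
  cause("VAs-01.06", "Measles", "VAs-01", "B05", "B05"),
  cause("VAs-01.07", "Meningitis and encephalitis", "VAs-01",
        c("G03", "G04"), c("A39", "G00-G05")),
  cause("VAs-01.08", "Tetanus", "VAs-01",
        c("A35", "A34|obstetric"), "A33-A35"),
  cause("VAs-01.09", "Pulmonary tuberculosis", "VAs-01", "A16", "A15-A16"),
  cause("VAs-01.10", "Pertussis", "VAs-01", "A37", "A37"),
  cause("VAs-01.11", "Haemorrhagic fever", "VAs-01", "A99", "A90-A99"),
  cause("VAs-01.99", "Other and unspecified infectious disease", "VAs-01",
        "B99", c("A20-A38", "A42-A89", "B00-B19", "B25-B49", "B55-B99")),
  cause("VAs-98", "Other and unspecified non-communicable disease", "VAs-98",
        "R99",
        c("D55-D89", "E00-E07", "E15-E35", "E50-E90", "F00-F99", "G10-G37",
          "G50-G99", "H00-H95", "J30-J39", "J47-J99", "K00-K31", "K40-K93",
          "L00-L99", "M00-M99", "N00-N16", "N20-N99", "R00-R69")),
  cause("VAs-02.01", "Oral neoplasms", "VAs-02", "C06", "C00-C06"),
  cause("VAs-02.02", "Digestive neoplasms", "VAs-02", "C26", "C15-C26"),
  cause("VAs-02.03", "Respiratory neoplasms", "VAs-02", "C39", "C30-C39"),
  cause("VAs-02.04", "Breast neoplasms", "VAs-02", "C50", "C50"),
  cause("VAs-02.05", "Female reproductive neoplasms", "VAs-02", "C57",
        "C51-C58"),
  cause("VAs-02.06", "Male reproductive neoplasms", "VAs-02", "C63",
        "C60-C63"),
  cause("VAs-02.99", "Other and unspecified neoplasms", "VAs-02", "C80",
        c("C07-C14", "C40-C49", "C60-D48")),
  cause("VAs-03.01", "Severe anaemia", "VAs-03", "D64", "D50-D64"),
  cause("VAs-03.02", "Severe malnutrition", "VAs-03", "E46", "E40-E46"),
  cause("VAs-03.03", "Diabetes mellitus", "VAs-03", "E14", "E10-E14"),
  cause("VAs-04.01", "Acute cardiac disease", "VAs-04",
        c("I24", "I24|acute_ischemic"), "I20-I25"),
  cause("VAs-04.02", "Stroke", "VAs-04", "I64", "I60-I69"),
  cause("VAs-04.03", "Sickle cell with crisis", "VAs-04", "D57", "D57"),
  cause("VAs-04.99", "Other and unspecified cardiac disease", "VAs-04",
        "I99", c("I10-I15", "I26-I52", "I70-I99")),
  cause("VAs-05.01", "Chronic obstructive pulmonary disease (COPD)",
        "VAs-05", "J44", "J40-J44"),
  cause("VAs-05.02", "Asthma", "VAs-05",
        c("J45", "J46|status_asthmaticus"), "J45-J46"),
  cause("VAs-06.01", "Acute abdomen", "VAs-06", "R10", "R10"),
  cause("VAs-06.02", "Liver cirrhosis", "VAs-06", "K74", "K70-K76"),
  cause("VAs-07.01", "Renal failure", "VAs-07", "N19", "N17-N19"),
  cause("VAs-08.01", "Epilepsy", "VAs-08", "G40", "G40-G41"),
  cause("VAs-09.01", "Ectopic pregnancy", "VAs-09", "O00", "O00"),
  cause("VAs-09.02", "Abortion-related death", "VAs-09", "O06", "O03-O08"),
  cause("VAs-09.03", "Pregnancy-induced hypertension", "VAs-09",
        c("O13", "O15|eclampsia"), "O10-O16"),
  cause("VAs-09.04", "Obstetric haemorrhage", "VAs-09",
        c("O46|antepartum", "O72|postpartum"), c("O46", "O67", "O72")),
  cause("VAs-09.05", "Obstructed labour", "VAs-09", "O66", "O63-O66"),
  cause("VAs-09.06", "Pregnancy-related sepsis", "VAs-09",
        c("O75.3|antepartum", "O85|postpartum"), c("O85", "O75.3")),
  cause("VAs-09.07", "Anaemia of pregnancy", "VAs-09", "O99", "O99.0"),
  cause("VAs-09.08", "Ruptured uterus", "VAs-09", "O71", "O71"),
  cause("VAs-09.99", "Other and unspecified maternal cause", "VAs-09", "O05",
        c("O01-O02", "O20-O45", "O47-O62", "O68-O70", "O73-O84", "O86-O99")),
  cause("VAs-10.01", "Prematurity", "VAs-10", "P07", "P05-P07"),
  cause("VAs-10.02", "Birth asphyxia", "VAs-10", "P21", "P20-P22"),
  cause("VAs-10.03", "Neonatal pneumonia", "VAs-10", "P23", "P23-P25"),
  cause("VAs-10.04", "Neonatal sepsis", "VAs-10", "P63", "P36",
        notes = paste("Certification code stored verbatim as published (P63)",
                      "although it conflicts with the from-range P36",
                      "(neonatal sepsis); mapping uses from_icd only.")),
  cause("VAs-10.05", "Neonatal tetanus", "VAs-10", "A33", "A33"),
  cause("VAs-10.06", "Congenital malformation", "VAs-10", "Q89", "Q00-Q99"),
  cause("VAs-10.99", "Other and unspecified perinatal cause of death",
        "VAs-10", "P96",
        c("P00-P04", "P08-P15", "P26-P35", "P37-P94", "P96")),
  cause("VAs-11.01", "Fresh stillbirth", "VAs-11", "P95", "P95"),
  cause("VAs-11.02", "Macerated stillbirth", "VAs-11", "P95", "P95"),
  cause("VAs-12.01", "Road traffic accident", "VAs-12", "V89", "V01-V89"),
  cause("VAs-12.02", "Other transport accident", "VAs-12", "V99", "V90-V99"),
  cause("VAs-12.03", "Accidental fall", "VAs-12", "W19", "W00-W19"),
  cause("VAs-12.04", "Accidental drowning and submersion", "VAs-12", "W74",
        "W65-W74"),
  cause("VAs-12.05", "Accidental exposure to smoke, fire and flames",
        "VAs-12", "X09", "X00-X19"),
  cause("VAs-12.06", "Contact with venomous animals and plants", "VAs-12",
        "X29", "X20-X29"),
  cause("VAs-12.07", "Accidental poisoning and exposure to noxious substance",
        "VAs-12", "X49", "X40-X49"),
  cause("VAs-12.08", "Intentional self-harm", "VAs-12", "X84", "X60-X84"),
  cause("VAs-12.09", "Assault", "VAs-12", "Y09", "X85-Y09"),
  cause("VAs-12.10", "Exposure to force of nature", "VAs-12", "X39",
        "X30-X39"),
  cause("VAs-12.99", "Other and unspecified external cause of death",
        "VAs-12", "X59",
        c("S00-T99", "W20-W64", "W75-W99", "X50-X59", "Y10-Y98")),
  cause("VA-99", "Cause of death unknown", "VA-99", "R99", "R99",
        is_cause = FALSE)
)

stopifnot(length(causes) == 63L,
          sum(vapply(causes, `[[`, TRUE, "is_cause")) == 62L)

## -------------------------------------------------------- indicator registry

# Published pattern of CoD-related indicators (distinct items shared across
# age groups):
#   skip level        1    2    3    4     total
#   adult (15+)      56   37   27   10      130
#   child (4wk-14y)  34   35   22   10      101
#   neonate (<28d)   44   35   15   10      104
#   distinct         93   87   31   10      221
# plus, per age group: 26 personal, 3 respondent, 10 context (gate-free).
#
# Sharing structure chosen to realise those distinct counts:
#   L1: 15 all-three, 6 adult+child, 5 adult+neonate,
#       30 adult-only, 13 child-only, 24 neonate-only            -> 93
#   L2: 10 all-three, 27 adult-only, 25 child-only, 25 neonate-only -> 87
#   L3: 15 all-three, 3 adult+child, 9 adult-only, 4 child-only  -> 31
#   L4: 10 all-three                                             -> 10
# A maternal block (1 L1 screening gate + 8 L2 + 4 L3 descendants, all
# adult-only) realises the 130-question maternal maximum.

label_pool <- c(
  "fever", "cough", "difficulty breathing", "diarrhoea", "vomiting",
  "abdominal pain", "headache", "stiff neck", "convulsions",
  "unconsciousness", "rash", "weight loss", "swelling", "jaundice",
  "pallor", "chest pain", "night sweats", "bleeding", "injury",
  "paralysis", "difficulty swallowing", "urinary complaint", "mass or lump",
  "oedema of legs", "confusion", "skin lesion", "wasting", "thirst",
  "breathlessness on exertion", "blue lips or skin")

mk_label <- function(level, k) {
  base <- label_pool[((k - 1L) %% length(label_pool)) + 1L]
  if (level == 1L) sprintf("screen: %s", base)
  else sprintf("detail L%d: %s (item %d)", level, base, k)
}

indicators <- list()
counter <- 0L
add_ind <- function(level, n, age_groups, parents, maternal = FALSE,
                    prefix = "cod") {
  # round-robin parent assignment keeps the tree shallow and balanced
  ids <- character(n)
  for (k in seq_len(n)) {
    counter <<- counter + 1L
    id <- sprintf("%s_%04d", prefix, counter)
    parent <- if (length(parents)) parents[((k - 1L) %% length(parents)) + 1L]
              else ""
    indicators[[length(indicators) + 1L]] <<- list(
      indicator_id = id,
      label = mk_label(level, counter),
      category = "cod_related",
      skip_level = level,
      age_groups = as.list(age_groups),
      parent_id = parent,
      maternal = maternal)
    ids[k] <- id
  }
  ids
}

ALL <- c("adult", "child", "neonate")

t1  <- add_ind(1L, 15L, ALL, character())
ac1 <- add_ind(1L, 6L, c("adult", "child"), character())
an1 <- add_ind(1L, 5L, c("adult", "neonate"), character())
# first adult-only L1 item is the maternal screening gate
mat_gate <- add_ind(1L, 1L, "adult", character(), maternal = TRUE)
a1  <- add_ind(1L, 29L, "adult", character())
c1  <- add_ind(1L, 13L, "child", character())
n1  <- add_ind(1L, 24L, "neonate", character())

t2      <- add_ind(2L, 10L, ALL, t1)
a2_mat  <- add_ind(2L, 8L, "adult", mat_gate, maternal = TRUE)
a2      <- add_ind(2L, 19L, "adult", c(a1, ac1, an1))
c2      <- add_ind(2L, 25L, "child", c(c1, ac1))
n2      <- add_ind(2L, 25L, "neonate", c(n1, an1))

t3      <- add_ind(3L, 15L, ALL, t2)
ac3     <- add_ind(3L, 3L, c("adult", "child"), t2)
a3_mat  <- add_ind(3L, 4L, "adult", a2_mat, maternal = TRUE)
a3      <- add_ind(3L, 5L, "adult", a2)
c3      <- add_ind(3L, 4L, "child", c2)

t4      <- add_ind(4L, 10L, ALL, t3)

# gate-free blocks shared by all age groups
personal_labels <- c(
  "name of deceased", "sex", "date of birth", "date of death", "age at death",
  "place of death", "place of usual residence", "marital status",
  "educational level", "occupation", "ethnic group", "citizenship",
  "death registered", "death certificate issued", "burial within 24h",
  "mother's name", "father's name", "household head", "household size",
  "region of residence", "urban or rural residence", "religion",
  "identification number", "season of death", "duration of final illness",
  "care sought before death")
respondent_labels <- c("respondent relationship to deceased",
                       "respondent lived with deceased",
                       "respondent present during final illness")
context_labels <- c(
  "recent contact with person with similar illness", "local disease outbreak",
  "recent travel", "access to health facility", "used mosquito net",
  "known chronic condition in household", "water source", "food shortage",
  "conflict or displacement in area", "animal contact")

add_flat <- function(category, labels, prefix) {
  for (k in seq_along(labels)) {
    indicators[[length(indicators) + 1L]] <<- list(
      indicator_id = sprintf("%s_%02d", prefix, k),
      label = labels[k],
      category = category,
      skip_level = NULL,
      age_groups = as.list(ALL),
      parent_id = "",
      maternal = FALSE)
  }
}
add_flat("personal", personal_labels, "per")
add_flat("respondent", respondent_labels, "res")
add_flat("context", context_labels, "ctx")

## ----------------------------------------------------------- subsumption map

subsumption <- list(
  list(cause_2007 = "Other digestive disease", target_va_code = "VAs-98"),
  list(cause_2007 = "Typhoid and paratyphoid", target_va_code = "VAs-01.99"),
  list(cause_2007 = "Viral hepatitis", target_va_code = "VAs-01.99"),
  list(cause_2007 = "Leishmaniasis", target_va_code = "VAs-01.99"),
  list(cause_2007 = "Malignant melanoma of skin", target_va_code = "VAs-02.99"),
  list(cause_2007 = "Malignant neoplasm of lymphoid, haematopoietic and related tissue",
       target_va_code = "VAs-02.99"),
  list(cause_2007 = "Other specified neoplasms", target_va_code = "VAs-02.99"),
  list(cause_2007 = "Other specified endocrine disorders", target_va_code = "VAs-98"),
  list(cause_2007 = "Endocrine disorders, unspecified", target_va_code = "VAs-98"),
  list(cause_2007 = "Other specified diseases of the respiratory system",
       target_va_code = "VAs-98"),
  list(cause_2007 = "Respiratory disorder, unspecified", target_va_code = "VAs-98"),
  list(cause_2007 = "Respiratory failure, not elsewhere classified",
       target_va_code = "VAs-98"),
  list(cause_2007 = "Other diseases of intestine", target_va_code = "VAs-98"),
  list(cause_2007 = "Disease of intestine, unspecified", target_va_code = "VAs-98"),
  list(cause_2007 = "Specified mental disorders", target_va_code = "VAs-98"),
  list(cause_2007 = "Mental disorders, unspecified", target_va_code = "VAs-98"),
  list(cause_2007 = "Other specified disorders of the nervous system",
       target_va_code = "VAs-98"),
  list(cause_2007 = "Nervous system disorders, not otherwise classified",
       target_va_code = "VAs-98"),
  list(cause_2007 = "Alzheimer's disease", target_va_code = "VAs-98"),
  list(cause_2007 = "Other specified direct maternal causes",
       target_va_code = "VAs-09.99"),
  list(cause_2007 = "Congenital viral diseases", target_va_code = "VAs-01.99"),
  list(cause_2007 = "Congenital malformations of the nervous system",
       target_va_code = "VAs-10.06"),
  list(cause_2007 = "Other specified disorders related to perinatal period",
       target_va_code = "VAs-10.99"),
  list(cause_2007 = "Lack of food and/or water", target_va_code = "VAs-12.99"),
  list(cause_2007 = "Legal intervention", target_va_code = "VAs-12.99"),
  list(cause_2007 = "Accident, unspecified", target_va_code = "VAs-12.99"),
  list(cause_2007 = "Other specified event, undetermined intent",
       target_va_code = "VAs-12.99")
)
stopifnot(length(subsumption) == 27L)

## --------------------------------------------------------------- constants

constants <- list(
  n_causes_2007 = 106L, n_causes_2012 = 62L,
  n_indicators_2007 = 408L, n_indicators_2012 = 221L,
  n_retained = 164L, n_new = 57L, n_excluded = 244L,
  per_level_distinct = list(`1` = 93L, `2` = 87L, `3` = 31L, `4` = 10L),
  per_group = list(
    adult   = list(levels = list(56L, 37L, 27L, 10L), cod_total = 130L,
                   personal = 26L, respondent = 3L, context = 10L,
                   total = 169L),
    child   = list(levels = list(34L, 35L, 22L, 10L), cod_total = 101L,
                   personal = 26L, respondent = 3L, context = 10L,
                   total = 140L),
    neonate = list(levels = list(44L, 35L, 15L, 10L), cod_total = 104L,
                   personal = 26L, respondent = 3L, context = 10L,
                   total = 143L))
)

write_json(causes, file.path(out_dir, "causes.json"),
           auto_unbox = TRUE, pretty = TRUE, null = "null")
write_json(indicators, file.path(out_dir, "indicators.json"),
           auto_unbox = TRUE, pretty = TRUE, null = "null")
write_json(subsumption, file.path(out_dir, "subsumption.json"),
           auto_unbox = TRUE, pretty = TRUE, null = "null")
write_json(constants, file.path(out_dir, "constants.json"),
           auto_unbox = TRUE, pretty = TRUE, null = "null")

cat("wrote", length(causes), "causes,", length(indicators), "indicators,",
    length(subsumption), "subsumption entries\n")
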