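# Terminology: code lists for every drug class and condition the criteria
# reference, dose-equivalence tables, heart-failure target doses and the
# tunable clinical conventions. Codes are opaque lowercase strings (no
# binding to real dictionaries such as dm+d or Read v2); deployers edit the
# shipped JSON to bind their own coding system.

#' Default terminology registry
#'
#' Builds the shipped terminology: drug/condition code sets, the class
#' groups used for drug-count predicates, dose-equivalence tables (statins
#' in simvastatin-equivalents, strong opioids in oral-morphine
#' equivalents), heart-failure target daily doses, and clinical convention
#' parameters (low-dose aspirin cut-off, observation lookbacks, CHADS2
#' point weights).
#'
#' @return A `dqip_terminology` object (a named list).
#' @export
default_terminology <- function() {
  ds <- function(id, ...) list(set_id = id, kind = "drug",
                               codes = c(...))
  cs <- function(id, ...) list(set_id = id, kind = "condition",
                               codes = c(...))

  thiazide <- c("bendroflumethiazide", "indapamide", "hydrochlorothiazide")
  loop <- c("furosemide", "bumetanide")
  k_sparing <- c("spironolactone", "eplerenone", "amiloride", "triamterene")
  acei <- c("ramipril", "lisinopril", "enalapril", "perindopril")
  arb <- c("losartan", "candesartan", "irbesartan")
  ccb <- c("amlodipine", "felodipine", "nifedipine", "lercanidipine",
           "nicardipine", "diltiazem", "verapamil")
  bb <- c("atenolol", "bisoprolol", "carvedilol", "metoprolol",
          "propranolol", "nebivolol", "sotalol")
  alpha <- c("doxazosin")
  other_antihtn <- c("methyldopa", "moxonidine")
  sulphonylurea <- c("gliclazide", "tolbutamide", "glibenclamide",
                     "glimepiride", "chlorpropamide")
  glitazone <- c("pioglitazone", "rosiglitazone")
  metformin <- "metformin"
  dpp4 <- c("sitagliptin")
  cox2 <- c("celecoxib", "etoricoxib")
  nsaid_ns <- c("ibuprofen", "naproxen", "diclofenac", "indometacin",
                "piroxicam", "mefenamic_acid")
  estrogen_only <- c("estradiol", "conjugated_estrogens")
  hrt_combined <- c("estradiol_norethisterone",
                    "estradiol_medroxyprogesterone", "tibolone")
  tca <- c("amitriptyline", "imipramine", "dosulepin", "clomipramine",
           "nortriptyline")
  antipsychotic <- c("haloperidol", "risperidone", "olanzapine",
                     "quetiapine", "clozapine", "chlorpromazine")
  laba <- c("salmeterol", "formoterol")
  ltra <- c("montelukast", "zafirlukast")
  theophylline <- c("theophylline", "aminophylline")
  bisphosphonate <- c("alendronate", "risedronate")

  sets <- list(
    # -- cardiovascular drugs --------------------------------------------
    ds("THIAZIDE", thiazide),
    ds("METOLAZONE", "metolazone"),
    ds("LOOP_DIURETIC", loop),
    ds("K_SPARING_DIURETIC", k_sparing),
    ds("ALDOSTERONE_ANTAGONIST", "spironolactone", "eplerenone"),
    ds("K_WASTING_DIURETIC", thiazide, "metolazone", loop),
    ds("DIURETIC", thiazide, "metolazone", loop, k_sparing),
    ds("K_SUPPLEMENT", "potassium_chloride"),
    ds("ACEI", acei),
    ds("ARB", arb),
    ds("ACEI_ARB", acei, arb),
    ds("CCB", ccb),
    ds("BETA_BLOCKER", bb),
    ds("BB_NONSELECTIVE", "propranolol", "carvedilol", "sotalol"),
    ds("BB_EYEDROPS", "timolol_eyedrops", "betaxolol_eyedrops"),
    ds("BB_LICENSED_CHF", "bisoprolol", "carvedilol", "nebivolol"),
    ds("ALPHA_BLOCKER", alpha),
    ds("ANTIHYPERTENSIVE", thiazide, acei, arb, ccb, bb, alpha,
       other_antihtn),
    ds("FIRSTLINE_ANTIHYPERTENSIVE", thiazide, acei, arb, "amlodipine",
       "felodipine", "nifedipine", "lercanidipine"),
    ds("VERAPAMIL_DILTIAZEM", "verapamil", "diltiazem"),
    ds("VERAPAMIL", "verapamil"),
    ds("MINOXIDIL", "minoxidil"),
    ds("DIGOXIN", "digoxin"),
    ds("AMIODARONE", "amiodarone"),
    ds("PROPAFENONE", "propafenone"),
    ds("ANTIARRHYTHMIC_1_3_NOT_AMIO", "flecainide", "propafenone",
       "disopyramide", "sotalol", "dronedarone"),
    ds("CCB_DIGOXIN_INTERACTING", "lercanidipine", "nicardipine",
       "nifedipine", "diltiazem", "verapamil"),
    ds("STATIN", "simvastatin", "atorvastatin", "rosuvastatin",
       "pravastatin", "fluvastatin"),
    ds("SIMVASTATIN", "simvastatin"),
    ds("FIBRATE_NOT_FENOFIBRATE", "gemfibrozil", "bezafibrate",
       "ciprofibrate"),
    # -- antithrombotics --------------------------------------------------
    ds("ASPIRIN", "aspirin"),
    ds("CLOPIDOGREL", "clopidogrel"),
    ds("DIPYRIDAMOLE", "dipyridamole"),
    ds("ANTIPLATELET", "aspirin", "clopidogrel", "dipyridamole"),
    ds("WARFARIN", "warfarin"),
    ds("ORAL_ANTICOAGULANT", "warfarin", "acenocoumarol", "phenindione"),
    ds("ANTITHROMBOTIC", "aspirin", "clopidogrel", "dipyridamole",
       "warfarin", "acenocoumarol", "phenindione"),
    # -- gastro / analgesia ----------------------------------------------
    ds("GIP", "omeprazole", "lansoprazole", "pantoprazole",
       "esomeprazole", "ranitidine", "misoprostol"),
    ds("COX2", cox2),
    ds("NSAID_NS_ORAL", nsaid_ns),
    ds("NSAID_ORAL", nsaid_ns, cox2),
    ds("PARACETAMOL", "paracetamol"),
    ds("OPIOID_STRONG", "morphine", "oxycodone", "hydromorphone",
       "fentanyl"),
    ds("LAXATIVE", "senna", "lactulose", "macrogol", "docusate",
       "bisacodyl"),
    ds("ALLOPURINOL", "allopurinol"),
    # -- anti-infectives interacting with warfarin ------------------------
    ds("MACROLIDE", "erythromycin", "clarithromycin", "azithromycin"),
    ds("SULFONAMIDE", "sulfamethoxazole", "co_trimoxazole"),
    ds("AZOLE_ANTIFUNGAL", "fluconazole", "itraconazole", "ketoconazole",
       "miconazole", "voriconazole"),
    ds("METRONIDAZOLE", "metronidazole"),
    ds("CHLORAMPHENICOL", "chloramphenicol"),
    ds("ISONIAZID", "isoniazid"),
    ds("RIFAMPICIN", "rifampicin"),
    ds("GRISEOFULVIN", "griseofulvin"),
    ds("RIBAVIRIN", "ribavirin"),
    ds("TETRACYCLINE", "tetracycline", "doxycycline", "minocycline",
       "oxytetracycline", "lymecycline"),
    ds("CHLOROQUINE_HCQ", "chloroquine", "hydroxychloroquine"),
    ds("QUININE", "quinine"),
    ds("HIV_PROTEASE_INHIBITOR", "ritonavir", "saquinavir", "indinavir"),
    ds("CICLOSPORIN", "ciclosporin"),
    ds("ITRACONAZOLE", "itraconazole"),
    ds("ANTIFUNGAL_SYSTEMIC_OTHER", "ketoconazole", "fluconazole",
       "voriconazole"),
    # -- diabetes ---------------------------------------------------------
    ds("METFORMIN", metformin),
    ds("SULPHONYLUREA", sulphonylurea),
    ds("SULPHONYLUREA_LONG_ACTING", "glibenclamide", "glimepiride",
       "chlorpropamide"),
    ds("GLITAZONE", glitazone),
    ds("ANTIDIABETIC_ORAL", metformin, sulphonylurea, glitazone, dpp4,
       "acarbose"),
    # -- respiratory ------------------------------------------------------
    ds("SABA", "salbutamol", "terbutaline"),
    ds("LABA", laba),
    ds("BETA_AGONIST_INHALER", "salbutamol", "terbutaline", laba),
    ds("LTRA", ltra),
    ds("THEOPHYLLINE", theophylline),
    ds("STEP3_ASTHMA_DRUG", laba, ltra, theophylline),
    ds("ICS", "beclometasone_inhaler", "budesonide_inhaler",
       "fluticasone_inhaler"),
    ds("ANTIMUSCARINIC_INHALER", "tiotropium", "ipratropium"),
    ds("LABA_OR_ANTIMUSCARINIC_INHALER", laba, "tiotropium", "ipratropium"),
    ds("PREDNISOLONE_ORAL", "prednisolone"),
    ds("CORTICOSTEROID_ORAL", "prednisolone", "dexamethasone"),
    # -- bone / hormones --------------------------------------------------
    ds("BONE_PROTECT_OSTEOPOROSIS", bisphosphonate, "strontium_ranelate",
       "raloxifene", "teriparatide"),
    ds("BONE_PROTECT_STEROID", bisphosphonate, "calcitriol", estrogen_only,
       hrt_combined),
    ds("CALCIUM_VITD", "calcium_colecalciferol", "calcium_ergocalciferol"),
    ds("ESTROGEN_ONLY_HRT", estrogen_only),
    ds("HRT_COMBINED", hrt_combined),
    ds("HRT_ANY", estrogen_only, hrt_combined),
    ds("PROGESTOGEN_CYCLICAL", "norethisterone", "medroxyprogesterone"),
    ds("CONTRACEPTIVE_COMBINED", "ethinylestradiol_levonorgestrel",
       "ethinylestradiol_desogestrel"),
    # -- DMARDs -----------------------------------------------------------
    ds("METHOTREXATE", "methotrexate"),
    ds("AURANOFIN", "auranofin"),
    ds("AUROTHIOMALATE", "aurothiomalate"),
    ds("PENICILLAMINE", "penicillamine"),
    ds("LEFLUNOMIDE", "leflunomide"),
    ds("AZATHIOPRINE", "azathioprine"),
    ds("CYCLOPHOSPHAMIDE", "cyclophosphamide"),
    ds("SULFASALAZINE", "sulfasalazine"),
    # -- CNS and elderly-risk drugs --------------------------------------
    ds("TCA", tca),
    ds("ANTIPSYCHOTIC", antipsychotic),
    ds("RISPERIDONE", "risperidone"),
    ds("ANTIPSYCHOTIC_NOT_RISPERIDONE",
       setdiff(antipsychotic, "risperidone")),
    ds("ANTIPSYCHOTIC_NOT_QUETIAPINE_CLOZAPINE",
       setdiff(antipsychotic, c("quetiapine", "clozapine"))),
    ds("BENZO_LONG_ACTING", "diazepam", "chlordiazepoxide", "nitrazepam"),
    ds("BENZO_SHORT_ACTING", "temazepam", "lorazepam", "oxazepam"),
    ds("Z_DRUG", "zopiclone", "zolpidem", "zaleplon"),
    ds("ANTIHISTAMINE_ANTIMUSCARINIC", "chlorphenamine", "hydroxyzine",
       "promethazine", "diphenhydramine"),
    ds("ANTISPASMODIC_ANTIMUSCARINIC", "hyoscine", "dicycloverine",
       "propantheline"),
    ds("UROLOGICAL_ANTIMUSCARINIC", "oxybutynin", "tolterodine",
       "solifenacin"),
    ds("PHENOTHIAZINE_ANTIEMETIC", "prochlorperazine", "promethazine"),
    ds("GLITAZONE", glitazone),
    ds("TADALAFIL", "tadalafil"),
    ds("DISULFIRAM", "disulfiram"),
    ds("FLUOXETINE", "fluoxetine"),
    ds("ANTIDEPRESSANT_NOT_FLUOXETINE", "citalopram", "sertraline",
       "paroxetine", "venlafaxine", "mirtazapine", tca),
    # -- condition sets ---------------------------------------------------
    cs("HYPERTENSION", "htn"),
    cs("HTN_COMPLICATION", "chd", "angina", "mi", "acs", "stroke", "tia",
       "pvd", "ckd3", "ckd4", "ckd5", "dm1", "dm2", "lvh"),
    cs("CHD", "chd", "angina", "mi", "acs"),
    cs("ANGINA", "angina"),
    cs("ACS", "acs", "mi"),
    cs("VASCULAR_EVENT", "mi", "stroke", "tia"),
    cs("STROKE_TIA", "stroke", "tia"),
    cs("PVD", "pvd"),
    cs("VASCULAR_DISEASE_ANY", "mi", "stroke", "tia", "chd", "angina",
       "acs", "pvd"),
    cs("DIABETES", "dm1", "dm2"),
    cs("DIABETES_T2", "dm2"),
    cs("MICROALBUMINURIA", "microalbuminuria"),
    cs("OVERWEIGHT", "overweight", "obesity"),
    cs("CHF", "chf"),
    cs("AF", "af"),
    cs("ASTHMA", "asthma"),
    cs("COPD", "copd"),
    cs("OSTEOPOROSIS", "osteoporosis"),
    cs("VERTEBRAL_FRACTURE", "vertebral_fracture"),
    cs("LOW_TRAUMA_FRACTURE", "low_trauma_fracture", "vertebral_fracture"),
    cs("PEPTIC_ULCER", "peptic_ulcer"),
    cs("GOUT", "gout"),
    cs("CKD3", "ckd3"), cs("CKD4", "ckd4"), cs("CKD5", "ckd5"),
    cs("OSTEOARTHRITIS", "osteoarthritis"),
    cs("MINOR_TRAUMA", "minor_trauma", "sprain"),
    cs("DEMENTIA", "dementia"),
    cs("PSYCHOSIS", "psychosis", "schizophrenia"),
    cs("PARKINSONS", "parkinsons"),
    cs("KAWASAKI", "kawasaki")
  )
  ids <- map_chr(sets, "set_id")
  sets <- sets[!duplicated(ids)]
  names(sets) <- map_chr(sets, "set_id")

  term <- list(
    code_sets = sets,
    class_groups = list(
      antihypertensive_classes = c("THIAZIDE", "ACEI", "ARB", "CCB",
                                   "BETA_BLOCKER", "ALPHA_BLOCKER"),
      antidiabetic_classes = c("METFORMIN", "SULPHONYLUREA", "GLITAZONE")
    ),
    dose_equivalence = list(
      statin_simvastatin = list(
        reference_drug = "simvastatin", unit = "mg/day",
        factors = list(simvastatin = 1, atorvastatin = 2, rosuvastatin = 4,
                       pravastatin = 0.5, fluvastatin = 0.5)),
      opioid_morphine = list(
        reference_drug = "morphine", unit = "mg/day",
        factors = list(morphine = 1, oxycodone = 1.5, hydromorphone = 5,
                       fentanyl = 150))
    ),
    # heart-failure target daily doses, mg/day
    target_daily_dose = list(
      ramipril = 10, lisinopril = 35, enalapril = 20, perindopril = 8,
      losartan = 150, candesartan = 32, irbesartan = 300,
      bisoprolol = 10, carvedilol = 50, nebivolol = 10
    ),
    params = list(
      low_dose_aspirin_max_mg = 150,       # UK antiplatelet convention
      obs_lookback_weeks = 65,             # ~15-month review cycle (BP/HbA1c)
      intensification_response_weeks = 12, # time allowed to act on a result
      overweight_bmi = 25,
      chads2_weights = list(chf = 1, hypertension = 1, age_gt_75 = 1,
                            diabetes = 1, stroke_tia = 2),
      chads2_age_threshold = 75
    )
  )
  structure(term, class = "dqip_terminology")
}

#' Look up a code set
#'
#' @param terminology A `dqip_terminology`.
#' @param set_id Registered set identifier (e.g. `"NSAID_ORAL"`, `"GIP"`).
#' @return Character vector of member codes. An unknown id is an error,
#'   never an empty default.
#' @export
members <- function(terminology, set_id) {
  s <- terminology$code_sets[[set_id]]
  if (is.null(s)) {
    abort(sprintf("unknown code set id: '%s'", set_id),
          class = "dqip_config_error")
  }
  s$codes
}

#' Convert a daily dose to reference-drug equivalents
#'
#' @param terminology A `dqip_terminology`.
#' @param table_id Equivalence table id (`"statin_simvastatin"` or
#'   `"opioid_morphine"` in the shipped data).
#' @param drug_code Drug code to convert.
#' @param daily_dose Daily dose in the table's unit.
#' @return `daily_dose * factor` in reference-drug units, or `NA` (with a
#'   "not assessable" signal downstream) when the drug has no factor.
#' @export
equivalent_daily_dose <- function(terminology, table_id, drug_code,
                                  daily_dose) {
  tab <- terminology$dose_equivalence[[table_id]]
  if (is.null(tab)) {
    abort(sprintf("unknown dose-equivalence table: '%s'", table_id),
          class = "dqip_config_error")
  }
  f <- tab$factors[[drug_code]]
  if (is.null(f)) return(NA_real_)
  daily_dose * f
}

active_condition_codes <- function(conditions, index_date) {
  if (is.null(conditions) || nrow(conditions) == 0) return(character())
  keep <- conditions$onset_date <= index_date &
    (is.na(conditions$resolved_date) | conditions$resolved_date > index_date)
  unique(conditions$code[keep])
}

#' CHADS2 stroke-risk score
#'
#' One point each for chronic heart failure, hypertension, diabetes and
#' age strictly greater than 75 at the index date; two points for prior
#' stroke or TIA. Point weights follow the standard published scheme and
#' are carried (editable) in the terminology parameters.
#'
#' @param conditions The patient's condition tibble (`code`, `onset_date`,
#'   optional `resolved_date`).
#' @param birth_date The patient's birth date.
#' @param index_date Date of assessment.
#' @param terminology A `dqip_terminology`.
#' @return Integer score in 0..6.
#' @export
chads2 <- function(conditions, birth_date, index_date,
                   terminology = default_terminology()) {
  codes <- active_condition_codes(conditions, index_date)
  w <- terminology$params$chads2_weights
  score <- 0L
  if (any(codes %in% members(terminology, "CHF"))) score <- score + w$chf
  if (any(codes %in% members(terminology, "HYPERTENSION")))
    score <- score + w$hypertension
  if (any(codes %in% members(terminology, "DIABETES")))
    score <- score + w$diabetes
  if (age_at(birth_date, index_date) > terminology$params$chads2_age_threshold)
    score <- score + w$age_gt_75
  if (any(codes %in% members(terminology, "STROKE_TIA")))
    score <- score + w$stroke_tia
  as.integer(score)
}

#' Chronic kidney disease stage at the index date
#'
#' A coded CKD stage (codes `ckd3`, `ckd4`, `ckd5`; the highest active
#' stage wins) takes precedence over the laboratory route. Otherwise the
#' latest eGFR observation is banded at standard cut-points: 30-59 stage 3,
#' 15-29 stage 4, below 15 stage 5, 60 or above no CKD.
#'
#' @inheritParams chads2
#' @param observations The patient's observation tibble.
#' @return `NA_integer_` (no CKD / not determinable) or 3L, 4L, 5L.
#' @export
ckd_stage <- function(conditions, observations, index_date,
                      terminology = default_terminology()) {
  codes <- active_condition_codes(conditions, index_date)
  coded <- c(if ("ckd5" %in% codes) 5L, if ("ckd4" %in% codes) 4L,
             if ("ckd3" %in% codes) 3L)
  if (length(coded)) return(max(coded))
  egfr <- latest_observation(observations, "eGFR", index_date)
  if (nrow(egfr) == 0) return(NA_integer_)
  v <- egfr$value[[1]]
  if (v >= 60) NA_integer_
  else if (v >= 30) 3L
  else if (v >= 15) 4L
  else 5L
}

#' Write / read a terminology registry as JSON
#'
#' @param terminology A `dqip_terminology`.
#' @param path File path.
#' @return `read_terminology()` returns a validated `dqip_terminology`;
#'   `write_terminology()` returns `path` invisibly.
#' @export
write_terminology <- function(terminology, path) {
  jsonlite::write_json(unclass(terminology), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_terminology
#' @export
read_terminology <- function(path = system.file("extdata",
                                                "terminology.json",
                                                package = "dqipr")) {
  raw <- jsonlite::read_json(path)
  need <- c("code_sets", "class_groups", "dose_equivalence",
            "target_daily_dose", "params")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    abort(sprintf("terminology file lacks section(s): %s",
                  paste(missing, collapse = ", ")),
          class = "dqip_config_error")
  }
  raw$code_sets <- lapply(raw$code_sets, function(s) {
    if (is.null(s$set_id) || is.null(s$kind) || is.null(s$codes)) {
      abort("malformed code set entry in terminology file",
            class = "dqip_config_error")
    }
    s$codes <- as.character(unlist(s$codes))
    s
  })
  raw$class_groups <- lapply(raw$class_groups, function(g)
    as.character(unlist(g)))
  for (tid in names(raw$dose_equivalence)) {
    tab <- raw$dose_equivalence[[tid]]
    facs <- unlist(tab$factors)
    if (any(facs <= 0)) {
      abort(sprintf("dose-equivalence table '%s' has non-positive factor",
                    tid), class = "dqip_config_error")
    }
    if (abs(facs[[tab$reference_drug]] - 1) > 1e-12) {
      abort(sprintf("reference drug factor must be 1 in table '%s'", tid),
            class = "dqip_config_error")
    }
  }
  structure(raw, class = "dqip_terminology")
}
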