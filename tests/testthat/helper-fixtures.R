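# Shared fixtures: a tiny hand-built cohort and toy coefficient sets with
# hand-computable outputs.

toy_patient <- function(patient_id = "P1", ascvd_subtype = "CAD",
                        ldl_c = 93, age = 68, sex = "male",
                        smoking = "non", diabetes = FALSE,
                        hypertension = FALSE, chf = FALSE, af = FALSE,
                        sbp = 135, dbp = 80, bmi = 28, ckd_ge3 = FALSE,
                        n_vascular_beds = 1, event_within_1y = FALSE,
                        region = "europe", statin_intensity = "high",
                        ezetimibe = FALSE, pcsk9i = FALSE,
                        other_llt = FALSE) {
  data.frame(patient_id = patient_id, ascvd_subtype = ascvd_subtype,
             ldl_c = ldl_c, age = age, sex = sex, smoking = smoking,
             diabetes = diabetes, hypertension = hypertension, chf = chf,
             af = af, sbp = sbp, dbp = dbp, bmi = bmi, ckd_ge3 = ckd_ge3,
             n_vascular_beds = n_vascular_beds,
             event_within_1y = event_within_1y, region = region,
             statin_intensity = statin_intensity, ezetimibe = ezetimibe,
             pcsk9i = pcsk9i, other_llt = other_llt,
             stringsAsFactors = FALSE)
}

toy_cohort <- function(ldl = c(50, 60, 80), subtype = "CAD") {
  do.call(rbind, lapply(seq_along(ldl), function(i)
    toy_patient(patient_id = sprintf("P%d", i), ldl_c = ldl[i],
                ascvd_subtype = if (length(subtype) == 1) subtype
                                else subtype[i])))
}

# Single-term coefficient set: only age matters, no centering.
toy_coeffs_age <- function(coef = 0.01, s0 = 0.95, reference = 0) {
  reach_coefficients(
    terms = list(age = list(coefficient = coef,
                            transform = list(type = "linear"))),
    baseline = list(form = "survival", value = s0,
                    reference_score = reference))
}

# Zero-score set: every patient sits at the reference, risk20 = 1 - s0.
toy_coeffs_flat <- function(s0 = 0.95) {
  reach_coefficients(
    terms = list(diabetes = list(coefficient = 0,
                                 transform = list(type = "binary"))),
    baseline = list(form = "survival", value = s0, reference_score = 0))
}
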