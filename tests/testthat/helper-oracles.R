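# Independent brute-force recomputations of every pipeline quantity, written
# as plain base-R loops over data-frame rows so they share no code path with
# the package's vectorised implementation.

oracle_need <- function(caseload, conditions) {
  out <- caseload
  out$decedents_in_need <- NA_real_
  out$nondecedents_in_need <- NA_real_
  for (i in seq_len(nrow(out))) {
    j <- which(conditions$code == out$condition[i])
    out$decedents_in_need[i] <-
      out$decedent_deaths[i] * conditions$decedent_need_fraction[j]
    out$nondecedents_in_need[i] <-
      out$nondecedent_cases[i] * conditions$nondecedent_need_fraction[j]
  }
  out[, c("country", "condition", "decedents_in_need",
          "nondecedents_in_need")]
}

# long (country, condition, status, n) form of a need table, by loop
oracle_need_long <- function(need) {
  rows <- list()
  for (i in seq_len(nrow(need))) {
    rows[[length(rows) + 1]] <- data.frame(
      country = need$country[i], condition = need$condition[i],
      status = "decedent", n = need$decedents_in_need[i])
    rows[[length(rows) + 1]] <- data.frame(
      country = need$country[i], condition = need$condition[i],
      status = "nondecedent", n = need$nondecedents_in_need[i])
  }
  do.call(rbind, rows)
}

oracle_burden <- function(need, coefs, weighting = "prevalence") {
  long <- oracle_need_long(need)
  countries <- unique(need$country)
  at_most <- setNames(numeric(length(countries)), countries)
  at_least <- setNames(numeric(length(countries)), countries)
  per_symptom <- list()
  for (i in seq_len(nrow(long))) {
    sel <- coefs$condition == long$condition[i] &
      coefs$status == long$status[i]
    if (!any(sel)) next
    sub <- coefs[sel, ]
    for (j in seq_len(nrow(sub))) {
      d <- long$n[i] * sub$prevalence[j] * sub$duration_days[j]
      at_most[long$country[i]] <- at_most[long$country[i]] + d
      key <- paste(long$country[i], sub$symptom[j], sep = "\r")
      per_symptom[[key]] <- (per_symptom[[key]] %||% 0) + d
    }
    # longest duration wins; ties to higher prevalence then first label
    ord <- order(-sub$duration_days, -sub$prevalence, sub$symptom)
    best <- sub[ord[1], ]
    contr <- if (weighting == "prevalence") {
      long$n[i] * best$prevalence * best$duration_days
    } else {
      long$n[i] * best$duration_days
    }
    at_least[long$country[i]] <- at_least[long$country[i]] + contr
  }
  list(at_most = at_most, at_least = at_least, per_symptom = per_symptom)
}

oracle_required <- function(need, coefs, params) {
  long <- oracle_need_long(need)
  countries <- unique(need$country)
  req <- setNames(numeric(length(countries)), countries)
  for (i in seq_len(nrow(long))) {
    if (!(identical(params$requirement_population, "decedents") &&
            long$status[i] != "decedent")) {
      sel <- coefs$condition == long$condition[i] &
        coefs$status == long$status[i] & coefs$symptom == "pain"
      if (any(sel)) {
        req[long$country[i]] <- req[long$country[i]] +
          long$n[i] * coefs$prevalence[sel] * coefs$duration_days[sel] *
          params$pain_daily_dose_mg
      }
    }
    if (long$status[i] == "decedent") {
      sel <- coefs$condition == long$condition[i] &
        coefs$status == "decedent" & coefs$symptom == "dyspnea"
      if (any(sel)) {
        req[long$country[i]] <- req[long$country[i]] +
          long$n[i] * coefs$prevalence[sel] * coefs$duration_days[sel] *
          params$dyspnea_daily_dose_mg
      }
    }
  }
  req
}

oracle_dome <- function(supply, eq) {
  countries <- unique(supply$country)
  dome <- setNames(numeric(length(countries)), countries)
  for (i in seq_len(nrow(supply))) {
    sel <- eq$opioid == supply$opioid[i] &
      eq$route_class == supply$route_class[i]
    if (!eq$is_methadone[sel]) {
      dome[supply$country[i]] <- dome[supply$country[i]] +
        supply$quantity_mg[i] * eq$ome_multiplier[sel]
    }
  }
  dome
}

oracle_encounters <- function(need, ecoefs) {
  long <- oracle_need_long(need)
  acc <- list()
  for (i in seq_len(nrow(long))) {
    sel <- which(ecoefs$condition == long$condition[i] &
                   ecoefs$status == long$status[i])
    for (j in sel) {
      key <- paste(long$country[i], ecoefs$level[j], sep = "\r")
      prev <- acc[[key]] %||% c(ip = 0, op = 0, hv = 0)
      acc[[key]] <- prev + c(
        ip = long$n[i] * ecoefs$inpatient_days_per_patient[j],
        op = long$n[i] * ecoefs$outpatient_visits_per_patient[j],
        hv = long$n[i] * ecoefs$home_visits_per_patient[j])
    }
  }
  acc
}

oracle_fte <- function(enc_acc, norms) {
  fte <- list()
  for (key in names(enc_acc)) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    level <- parts[2]
    e <- enc_acc[[key]]
    sel <- which(norms$level == level)
    for (j in sel) {
      k2 <- paste(parts[1], norms$staff_category[j], sep = "\r")
      hours <- e[["ip"]] * norms$hours_per_inpatient_day[j] +
        e[["op"]] * norms$hours_per_outpatient_visit[j] +
        e[["hv"]] * norms$hours_per_home_visit[j]
      fte[[k2]] <- (fte[[k2]] %||% 0) + hours / norms$annual_fte_hours[j]
    }
  }
  fte
}

`%||%` <- function(a, b) if (is.null(a)) b else a
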