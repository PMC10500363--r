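# Independent oracles used across the suite. These are deliberately written
# from the published definitions (per-item loops, full enumeration), not
# from the package's vectorised code paths.

# Fleiss (1971) kappa, straight from the published sums: loop over items,
# tally category counts, accumulate observed and chance agreement.
fleiss_brute <- function(ratings, categories = NULL) {
  if (is.null(categories)) categories <- sort(unique(as.vector(ratings)))
  N <- nrow(ratings)
  n <- ncol(ratings)
  k <- length(categories)
  P_sum <- 0
  cat_tot <- setNames(numeric(k), categories)
  for (i in seq_len(N)) {
    cnt <- setNames(numeric(k), categories)
    for (j in seq_len(n)) {
      cnt[[as.character(ratings[i, j])]] <- cnt[[as.character(ratings[i, j])]] + 1
    }
    P_sum <- P_sum + (sum(cnt^2) - n) / (n * (n - 1))
    cat_tot <- cat_tot + cnt
  }
  Pbar <- P_sum / N
  p_j <- cat_tot / (N * n)
  Pe <- sum(p_j^2)
  if (abs(1 - Pe) < 1e-14) return(NA_real_)
  (Pbar - Pe) / (1 - Pe)
}

# Exact two-sided Mann-Whitney p by full enumeration of which ranks go to
# group 1 (tie-free data only): p = min(1, 2 * min(P(U <= u), P(U >= u))).
mw_exact_brute <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  all_r <- seq_len(n1 + n2)
  u_all <- apply(combos, 2, function(ix) sum(all_r[ix]) - n1 * (n1 + 1) / 2)
  lo <- mean(u_all <= u_obs)
  hi <- mean(u_all >= u_obs)
  min(1, 2 * min(lo, hi))
}

# 100 common words with hand-tallied dictionary syllable counts, used to
# check the counter the way a hand-calculation validates automated scoring.
syllable_fixture <- function() {
  c(health = 1, doctor = 2, hospital = 3, patient = 2, medicine = 3,
    nurse = 1, surgery = 3, cancer = 2, screening = 2, symptom = 2,
    treatment = 2, therapy = 3, infection = 3, bacteria = 4, virus = 2,
    vaccine = 2, pregnancy = 3, delivery = 4, labor = 2, birth = 1,
    baby = 2, mother = 2, father = 2, family = 3, children = 2,
    woman = 2, body = 2, blood = 1, heart = 1, pressure = 2,
    weight = 1, exercise = 3, nutrition = 3, vitamin = 3, protein = 2,
    calcium = 3, water = 2, sleep = 1, stress = 1, anxiety = 4,
    depression = 3, pain = 1, fever = 2, cough = 1, headache = 2,
    stomach = 2, muscle = 2, bone = 1, skin = 1, tissue = 2,
    cell = 1, gene = 1, hormone = 2, insulin = 3, diabetes = 4,
    asthma = 2, allergy = 3, arthritis = 3, obesity = 4, anemia = 4,
    tumor = 2, biopsy = 3, diagnosis = 4, prognosis = 3, prevention = 3,
    recovery = 4, emergency = 4, ambulance = 3, clinic = 2, pharmacy = 3,
    prescription = 3, dosage = 2, tablet = 2, capsule = 2, injection = 3,
    needle = 2, bandage = 2, wound = 1, healing = 2, checkup = 2,
    appointment = 3, insurance = 3, benefit = 3, risk = 1, result = 2,
    normal = 2, common = 2, severe = 2, chronic = 2, acute = 2,
    gentle = 2, simple = 2, healthy = 2, important = 3, necessary = 4,
    possible = 3, available = 4, information = 4, question = 2, answer = 2)
}

# small deterministic config helpers ---------------------------------------

flat_cells <- function(n_per_source, topic = "pregnancy") {
  data.frame(
    source_category = c("government", "commercial", "nonprofit", "educational"),
    topic = topic,
    n = n_per_source,
    stringsAsFactors = FALSE
  )
}

# every sentence exactly `wps` words, `spd` sentences, monosyllabic easy
# words: closed-form surface statistics
degenerate_config <- function(seed = 1, spd = 10, wps = 12, n_docs = 1,
                              syllables = c(1, 0, 0, 0, 0),
                              hard_word_rate = 0) {
  generator_config(
    seed = seed,
    cells = data.frame(source_category = "government", topic = "pregnancy",
                       n = n_docs),
    sentences_per_doc = dist_spec(spd, 0, min = 1),
    words_per_sentence = dist_spec(wps, 0, min = 1),
    syllable_distribution = syllables,
    hard_word_rate = hard_word_rate
  )
}
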