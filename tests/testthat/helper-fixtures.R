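# Shared fixtures, built once per test session and cached. Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Small surrogate (4 channels up, 2 s records) for mechanical tests.
tiny_config <- function() {
  surrogate_config(channels = c(4L, 6L, 8L, 10L), input_samples = 500L,
                   input_rate = 250, seed = 7L)
}

tiny_model <- function() fixture("tiny_model", function() build_surrogate(tiny_config()))

tiny_records <- function(n = 8, seed = 300) {
  fixture(sprintf("tiny_records_%d_%d", n, seed), function() {
    lapply(seq_len(n), function(i)
      simulate_record(morphology_params(), fs = 250, duration_s = 2,
                      seed = seed + i, record_id = sprintf("t%03d", i)))
  })
}

mini_cohort <- function() {
  fixture("mini_cohort", function()
    simulate_cohort(8, 16, fs = 250, duration_s = 2, seed = 31))
}

# Default two-class cohort, n = 200 (50 LVSD / 150 non-LVSD).
default_cohort <- function() {
  fixture("default_cohort", function() simulate_cohort(50, 150, seed = 11))
}

# Cohort whose classes differ only in QRS width, plus a surrogate trained on
# it: the causal-TCAV experiment of the acceptance suite.
wq_cohort <- function() {
  fixture("wq_cohort", function()
    simulate_cohort(50, 150,
                    class_configs = single_trait_class_configs("qrs_width_ms"),
                    seed = 21))
}

wq_fit <- function() {
  fixture("wq_fit", function() {
    model <- build_surrogate(surrogate_config(seed = 5L))
    train_surrogate(model, wq_cohort(), train_config(epochs = 3L, seed = 2L))
  })
}

# Morphology archetypes for planted-structure recovery: five internally
# tight, mutually well-separated parameter distributions.
archetype_configs <- function() {
  list(
    wide = list(qrs_width_ms = c(160, 4, 150, 172),
                qrs_amplitude = c(0.70, 0.04, 0.62, 0.80),
                t_inversion_prob = 0, irregularity = c(0.01, 0.03),
                axis = c(30, 5, 15, 45), q_depth = c(1, 0.08, 0.8, 1.2),
                qt = c(1, 0.02, 0.95, 1.08), heart_rate = c(62, 4, 54, 72)),
    af = list(qrs_width_ms = c(82, 4, 72, 92),
              qrs_amplitude = c(1.05, 0.04, 0.95, 1.15),
              t_inversion_prob = 0, irregularity = c(0.32, 0.42),
              axis = c(55, 5, 40, 70), q_depth = c(1, 0.08, 0.8, 1.2),
              qt = c(1, 0.02, 0.95, 1.08), heart_rate = c(125, 5, 112, 140)),
    lowvolt = list(qrs_width_ms = c(95, 4, 85, 107),
                   qrs_amplitude = c(0.45, 0.03, 0.38, 0.53),
                   t_inversion_prob = 1, irregularity = c(0.01, 0.03),
                   axis = c(-50, 5, -65, -35), q_depth = c(3, 0.2, 2.5, 3.6),
                   qt = c(1.35, 0.03, 1.25, 1.45), heart_rate = c(55, 3, 48, 63)),
    tall = list(qrs_width_ms = c(90, 4, 80, 100),
                qrs_amplitude = c(1.8, 0.05, 1.65, 1.95),
                t_inversion_prob = 0, irregularity = c(0.01, 0.03),
                axis = c(85, 4, 72, 96), q_depth = c(1, 0.08, 0.8, 1.2),
                qt = c(1, 0.02, 0.95, 1.08), heart_rate = c(98, 4, 88, 110)),
    rbbb = list(qrs_width_ms = c(135, 4, 124, 146),
                qrs_amplitude = c(1.25, 0.04, 1.12, 1.36),
                t_inversion_prob = 1, irregularity = c(0.12, 0.18),
                axis = c(115, 5, 100, 130), q_depth = c(1.8, 0.15, 1.4, 2.2),
                qt = c(1.18, 0.02, 1.1, 1.25), heart_rate = c(82, 4, 72, 92)))
}

# Archetype subsets per planted count (chosen to be well separated in
# activation space; af and lowvolt carry internal substructure that would
# make a two-archetype world ambiguous).
archetype_names_for <- function(c) {
  switch(as.character(c),
         "2" = c("wide", "tall"),
         "3" = c("wide", "af", "lowvolt"),
         "5" = c("wide", "af", "lowvolt", "tall", "rbbb"))
}

archetype_records <- function(c, per = 25) {
  fixture(sprintf("archetype_records_%d", c), function() {
    arch <- archetype_configs()[archetype_names_for(c)]
    recs <- vector("list", c * per)
    lab <- integer(c * per)
    width <- numeric(c * per)
    for (i in seq_len(c * per)) {
      a <- ((i - 1) %% c) + 1L
      p <- ecgaudit:::with_seed(5000 + i,
        ecgaudit:::sample_morphology(arch[[a]]))
      recs[[i]] <- simulate_record(p, 250, 10, seed = 6000 + i,
                                   record_id = sprintf("arch%d_%03d", c, i))
      lab[i] <- a
      width[i] <- p$qrs_width_ms
    }
    list(records = recs, archetype = lab, qrs_width_ms = width)
  })
}

# Independent AUROC oracle: exhaustive pairwise comparison, ties 1/2.
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Independent AUPRC oracle: rank-walk average precision with tie groups.
auprc_rankwalk <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y); called <- seq_along(y)
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)  # tie groups end here
  prec <- (tp / called)[last_of_group]
  rec <- (tp / sum(y))[last_of_group]
  sum(diff(c(0, rec)) * prec)
}
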