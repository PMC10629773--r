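# Shared fixtures: all built in code, nothing on disk.

clique_edges <- function(v) t(utils::combn(v, 2))

two_cliques_graph <- function(k = 4) {
  sbm_graph(2 * k, rbind(clique_edges(seq_len(k)),
                         clique_edges(k + seq_len(k))))
}

path_graph <- function(n) {
  sbm_graph(n, cbind(seq_len(n - 1), 2:n))
}

star_graph <- function(n) {
  sbm_graph(n, cbind(1L, 2:n))
}

er_graph <- function(n, p, seed) {
  set.seed(seed)
  pr <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pr)) < p
  sbm_graph(n, t(pr[, keep, drop = FALSE]))
}

# Three-patient toy panel with hand-enumerable barcode.
toy_records <- function() {
  data.frame(
    patient_id = c("p1", "p2", "p3"),
    diagnosis = c("gbm", "astro", "astro"),
    age = c(60, 41, 39),
    sex = c("male", "female", "male"),
    survival_days = c(300L, 1500L, NA),
    event = c(1L, 0L, NA),
    IDH = c("wildtype", "IDH1 G395A", "IDH1 G395A"),
    MGMT = c("unmethylated", NA, ">25% methylation"),
    EGFR = c("high amplification", "no amplification", "no amplification"),
    `1p/19q` = c("no codeletion", "no codeletion", "no codeletion"),
    Histone = c("wildtype", "wildtype", "wildtype"),
    TERT = c("TERT C228T", "wildtype", "wildtype"),
    ATRX = c("retained", "loss of expression", NA),
    BRAF = c("wildtype", "wildtype", "wildtype"),
    check.names = FALSE, stringsAsFactors = FALSE)
}

# Two-subtype config with fully disjoint deterministic profiles.
two_subtype_config <- function(n, median_a = 300, median_b = 2000,
                               censor_rate = 0, survival_available = 1,
                               missing_probs = numeric()) {
  prof_a <- list(IDH = c(wildtype = 1), TERT = c(`TERT C228T` = 1),
                 ATRX = c(retained = 1), MGMT = c(unmethylated = 1),
                 EGFR = c(`high amplification` = 1),
                 `1p/19q` = c(`no codeletion` = 1),
                 Histone = c(wildtype = 1), BRAF = c(wildtype = 1))
  prof_b <- list(IDH = c(`IDH1 G395A` = 1), TERT = c(wildtype = 1),
                 ATRX = c(`loss of expression` = 1),
                 MGMT = c(`>25% methylation` = 1),
                 EGFR = c(`no amplification` = 1),
                 `1p/19q` = c(`1p/19q codeletion` = 1),
                 Histone = c(wildtype = 1), BRAF = c(wildtype = 1))
  synthetic_config(
    n,
    list(list(name = "A", prevalence = 0.5, profile = prof_a,
              hazard_scale = median_a / log(2), hazard_shape = 1),
         list(name = "B", prevalence = 0.5, profile = prof_b,
              hazard_scale = median_b / log(2), hazard_shape = 1)),
    missing_probs = missing_probs, censor_rate = censor_rate,
    survival_available = survival_available)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
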