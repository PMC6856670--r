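# Synthetic benchmark generator.
#
# Emulates the statistical structure the method assumes: drugs and diseases
# fall into matched clusters ("similar drugs treat related diseases"); each
# drug cluster has its own block of characteristic binary features per
# feature type; disease similarity is a two-level block matrix; associations
# are dense inside matched (drug cluster, disease cluster) blocks and sparse
# elsewhere. Only the geometry of the real inputs is emulated — marginal
# feature frequencies of real chemical/domain/annotation data are not.

#' Specification of a synthetic dataset
#'
#' Defaults describe the benchmark used throughout the package's tests: 60
#' drugs and 40 diseases in 3 matched clusters, 200 binary features per
#' feature type, characteristic features on with probability 0.6 inside the
#' owning cluster versus 0.05 background, disease similarity 0.8 within /
#' 0.1 between clusters, association density 0.5 inside matched blocks
#' against a 0.02 background rate.
#'
#' @param n_drugs,n_diseases,n_clusters entity and cluster counts.
#' @param n_features length-3 vector: features per type
#'   (chemical, domain, annotation).
#' @param feature_on_prob_in,feature_on_prob_out Bernoulli rates for
#'   cluster-characteristic features inside/outside the owning cluster;
#'   `in` must exceed `out`.
#' @param disease_sim_within,disease_sim_between block values of the disease
#'   similarity matrix; `within` must exceed `between`.
#' @param assoc_density_in,assoc_noise association probability for matched
#'   versus unmatched (drug, disease) cluster pairs; `in` must exceed the
#'   noise rate.
#' @param seed integer seed; generation is reproducible bit-for-bit.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_drugs = 60L, n_diseases = 40L, n_clusters = 3L,
                           n_features = c(chemical = 200L, domain = 200L,
                                          annotation = 200L),
                           feature_on_prob_in = 0.6,
                           feature_on_prob_out = 0.05,
                           disease_sim_within = 0.8,
                           disease_sim_between = 0.1,
                           assoc_density_in = 0.5, assoc_noise = 0.02,
                           seed = 7L) {
  if (n_clusters > n_drugs || n_clusters > n_diseases)
    stop("cluster count exceeds entity count")
  if (feature_on_prob_in <= feature_on_prob_out)
    stop("feature_on_prob_in must exceed feature_on_prob_out")
  if (disease_sim_within <= disease_sim_between)
    stop("disease_sim_within must exceed disease_sim_between")
  if (assoc_density_in <= assoc_noise)
    stop("assoc_density_in must exceed assoc_noise")
  structure(list(n_drugs = as.integer(n_drugs),
                 n_diseases = as.integer(n_diseases),
                 n_clusters = as.integer(n_clusters),
                 n_features = as.integer(n_features),
                 feature_on_prob_in = feature_on_prob_in,
                 feature_on_prob_out = feature_on_prob_out,
                 disease_sim_within = disease_sim_within,
                 disease_sim_between = disease_sim_between,
                 assoc_density_in = assoc_density_in,
                 assoc_noise = assoc_noise, seed = as.integer(seed)),
            class = "synthetic_spec")
}

balanced_clusters <- function(n, k) sort(rep_len(seq_len(k), n))

#' Generate a synthetic dataset bundle
#'
#' @param spec a [synthetic_spec()].
#' @return list with `features` (three [feature_table()]s), `D` (disease
#'   [similarity_matrix()]), `A` ([association_matrix()]), `truth` (the
#'   planted `drug_cluster` and `disease_cluster` assignments), and `spec`.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  with_seed(spec$seed, {
    n_dr <- spec$n_drugs; n_di <- spec$n_diseases; k <- spec$n_clusters
    drug_cl <- balanced_clusters(n_dr, k)
    dis_cl <- balanced_clusters(n_di, k)
    drug_ids <- sprintf("DR%03d", seq_len(n_dr))
    dis_ids <- sprintf("DI%03d", seq_len(n_di))
    types <- c("chemical", "domain", "annotation")
    features <- lapply(seq_along(types), function(t) {
      nf <- spec$n_features[t]
      feat_cl <- balanced_clusters(nf, k)    # disjoint characteristic blocks
      p <- matrix(spec$feature_on_prob_out, nf, n_dr)
      p[outer(feat_cl, drug_cl, "==")] <- spec$feature_on_prob_in
      vals <- matrix(stats::rbinom(nf * n_dr, 1L, p), nf, n_dr)
      dimnames(vals) <- list(sprintf("%s_%04d", toupper(types[t]), seq_len(nf)),
                             drug_ids)
      feature_table(vals, types[t])
    })
    names(features) <- types
    Dv <- matrix(spec$disease_sim_between, n_di, n_di)
    Dv[outer(dis_cl, dis_cl, "==")] <- spec$disease_sim_within
    diag(Dv) <- 1
    dimnames(Dv) <- list(dis_ids, dis_ids)
    p_assoc <- matrix(spec$assoc_noise, n_dr, n_di)
    p_assoc[outer(drug_cl, dis_cl, "==")] <- spec$assoc_density_in
    Av <- matrix(stats::rbinom(n_dr * n_di, 1L, p_assoc), n_dr, n_di)
    dimnames(Av) <- list(drug_ids, dis_ids)
    list(features = features, D = similarity_matrix(Dv),
         A = association_matrix(Av),
         truth = list(drug_cluster = stats::setNames(drug_cl, drug_ids),
                      disease_cluster = stats::setNames(dis_cl, dis_ids)),
         spec = spec)
  })
}

#' Hold out a fraction of known associations
#'
#' Removes `round(fraction * n_positives)` positives uniformly at random,
#' returning the masked training matrix and the held-out pairs. The union of
#' the training positives and the held-out pairs equals the original
#' positives.
#'
#' @param A an [association_matrix()].
#' @param fraction in (0, 1); at least one positive is removed and at least
#'   one must remain.
#' @param seed integer seed.
#' @return list with `A_train` and `held_out` (data frame: drug, disease).
#' @export
holdout_positives <- function(A, fraction, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  Av <- unclass(A)
  pos <- which(Av == 1)
  n_out <- max(1L, round(fraction * length(pos)))
  if (n_out >= length(pos))
    stop("holdout would remove every known association")
  with_seed(seed, {
    out <- sort(sample(pos, n_out))
    pairs <- arrayInd(out, dim(Av))
    held <- data.frame(drug = pairs[, 1], disease = pairs[, 2])
    list(A_train = mask_associations(A, held), held_out = held)
  })
}
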