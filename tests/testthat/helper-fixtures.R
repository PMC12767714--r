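# Minimal posterior / fit objects for entropy and information-criterion tests.
fake_posteriors <- function(indiv, group, group_index = NULL, weights = NULL,
                            joint = NULL) {
  indiv <- as.matrix(indiv); group <- as.matrix(group)
  structure(list(indiv_post = indiv, group_post = group,
                 joint_post = joint,
                 group_index = group_index %||% rep(1L, nrow(indiv)),
                 weights = weights %||% rep(1, nrow(indiv)),
                 map_indiv = max.col(indiv, ties.method = "first"),
                 map_group = max.col(group, ties.method = "first"),
                 group_ids = seq_len(nrow(group)),
                 K = ncol(indiv), M = ncol(group)),
            class = "mlca_posteriors")
}

fake_fit <- function(loglik, K, M, H, posteriors, N, J) {
  structure(list(loglik = loglik, K = K, M = M, H = H,
                 posteriors = posteriors, N = N, J = J),
            class = "mlca_fit")
}

# Tiny unit-record tibble wrapping an indicator matrix.
records_from_matrix <- function(y, group = rep(1L, nrow(y)), weight = NULL) {
  colnames(y) <- colnames(y) %||% paste0("s", seq_len(ncol(y)))
  dplyr::bind_cols(tibble::tibble(country_id = group,
                                  weight = weight %||% rep(1, nrow(y))),
                   tibble::as_tibble(y))
}

`%||%` <- rlang::`%||%`
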