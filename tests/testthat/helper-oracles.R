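# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths wherever the check is about correctness of those
# paths.

# brute-force energetic span: enumerate every (TS, preceding intermediate)
# pair and take the maximum difference; later TS wins ties
brute_force_barrier <- function(points) {
  pairs <- expand.grid(i = seq_len(nrow(points)), j = seq_len(nrow(points)))
  pairs <- pairs[pairs$j < pairs$i &
                   points$role[pairs$i] == "transition_state" &
                   points$role[pairs$j] %in% c("intermediate", "reactant"), ]
  spans <- points$G_rel[pairs$i] - points$G_rel[pairs$j]
  best_span <- max(spans)
  near <- which(spans > best_span - 1e-9)
  i <- max(pairs$i[near])                      # ties -> later TS
  pre <- which(seq_len(nrow(points)) < i &
                 points$role %in% c("intermediate", "reactant"))
  j <- pre[which.min(points$G_rel[pre])]
  list(span = best_span, ts = points$label[i], rest = points$label[j])
}

# random legal profile: alternating blocks of intermediates and TSs
random_profile <- function(n_ts = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- "M0"
  roles <- "intermediate"
  G <- 0
  for (k in seq_len(n_ts)) {
    labels <- c(labels, paste0("T", k), paste0("M", k))
    roles <- c(roles, "transition_state", "intermediate")
    G <- c(G, G[length(G)] + runif(1, 1, 25), G[length(G)] + runif(1, -15, 10))
  }
  gibbs_profile(data.frame(label = labels, role = roles, G_rel = G))
}

# CODATA constants, restated independently of the package's table
R_KCAL <- 1.987204258640832e-3
R_LATM <- 8.20573660809596e-2
KB <- 1.380649e-23
H <- 6.62607015e-34

hours16 <- 16 * 3600
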