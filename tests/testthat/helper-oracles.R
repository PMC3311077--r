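# Independent oracles and fixture builders shared across test files.

# Monte-Carlo estimate of the coincidence probability the Sulston score
# models: two band multisets drawn uniformly from G cells, P(>= M of the
# larger set's bands coincide with some band of the smaller set within the
# tolerance). The band space is treated as circular so that every band
# matches exactly 2t+1 cells, as the single-band coincidence probability
# (2t+1)/G assumes. Vectorised over trials.
mc_sulston <- function(n_lo, n_hi, M, G, tolerance = 0L, trials = 1e6,
                       seed = 1L) {
  stopifnot(M >= 1L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  A <- matrix(sample.int(G, trials * n_lo, replace = TRUE), trials, n_lo)
  B <- matrix(sample.int(G, trials * n_hi, replace = TRUE), trials, n_hi)
  matches <- integer(trials)
  for (j in seq_len(n_hi)) {
    hit <- rep(FALSE, trials)
    for (i in seq_len(n_lo)) {
      d <- abs(B[, j] - A[, i])
      hit <- hit | pmin(d, G - d) <= tolerance
    }
    matches <- matches + hit
  }
  p_hat <- mean(matches >= M)
  list(p = p_hat, se = sqrt(p_hat * (1 - p_hat) / trials))
}

# Exhaustive maximum one-to-one band matching within a tolerance (bipartite
# matching by recursion; fine for the small band sets used in tests).
brute_match_count <- function(a, b, tolerance) {
  if (length(a) == 0L || length(b) == 0L) return(0L)
  best <- 0L
  for (j in seq_along(b)) {
    if (abs(a[1] - b[j]) <= tolerance) {
      best <- max(best, 1L + brute_match_count(a[-1], b[-j], tolerance))
    }
  }
  max(best, brute_match_count(a[-1], b, tolerance))
}

# Brute-force N90/L90 by scanning all prefixes of the sorted lengths.
brute_n90_l90 <- function(lengths, reference_total) {
  s <- sort(lengths, decreasing = TRUE)
  total <- 0
  for (k in seq_along(s)) {
    total <- total + s[k]
    if (total >= 0.9 * reference_total) {
      return(list(n90 = s[k], l90 = k, reached = TRUE))
    }
  }
  list(n90 = NA_real_, l90 = NA_integer_, reached = FALSE)
}

# Brute-force connected components of the pass-cutoff graph over a
# fingerprint list (independent of the union-find in the package).
brute_components <- function(fps, cutoff, params) {
  n <- length(fps)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) {
      adj[i, j] <- sulston_score(fps[[i]], fps[[j]], params) <= cutoff &&
        match_count(fps[[i]], fps[[j]], params$tolerance) >= params$match
    }
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# Noiseless pool-level tag observations: a pool contains a tag iff one of
# its member clones digests to it.
noiseless_pool_tags <- function(pools, tags) {
  m <- merge(as.data.frame(pools)[, c("pool_id", "clone_id")],
             tags[, c("clone_id", "tag_sequence")], by = "clone_id")
  out <- unique(m[, c("pool_id", "tag_sequence")])
  out$n_reads <- 1L
  out
}

# A small clean study: repeat-free genome, clone library, digests and the
# provenance-true assignment (used where pooling noise is not under test).
clean_study <- function(genome_bp = 1e6, n_clones = 65, insert = 70000,
                        seed = 1) {
  g <- simulate_genome(genome_bp, te_fraction = 0, seed = seed)
  cl <- simulate_bac_library(g, n_clones, mean_insert = insert,
                             sd_insert = insert * 0.1, seed = seed + 1)
  tg <- clone_tags(g, cl)
  list(genome = g, clones = cl, tags = tg,
       assignment = wgpmap:::new_assignment(tg))
}

# Random synthetic wells on one plate with hand-built tag sets.
manual_plate <- function(n_clones, seed = 1) {
  set.seed(seed)
  wells <- sample(384L, n_clones)
  data.frame(clone_id = sprintf("mc_%02d", seq_len(n_clones)),
             plate = 1L,
             row = (wells - 1L) %/% 24L,
             col = (wells - 1L) %% 24L,
             start = 0L, end = 1L) |>
    (\(d) { class(d) <- c("wgp_clones", "data.frame"); d })()
}

random_tags <- function(n, len = 30, seed = 1) {
  set.seed(seed)
  unname(vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1)))
}
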