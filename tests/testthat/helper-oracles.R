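# Brute-force oracle for the dividing ratio: minimize the composite-space
# distance from the observed peak to points parameterized along the
# reference line, by grid search. Independent of the closed-form
# orthogonal projection it checks.
grid_search_fraction <- function(open_ref, closed_ref, observed,
                                 alpha_N = 0.14,
                                 t_range = c(-0.5, 1.5), step = 1e-6) {
  a <- c(open_ref[1], alpha_N * open_ref[2])
  b <- c(closed_ref[1], alpha_N * closed_ref[2])
  p <- c(observed[1], alpha_N * observed[2])
  ts <- seq(t_range[1], t_range[2], by = step)
  d2 <- (a[1] + ts * (b[1] - a[1]) - p[1])^2 +
        (a[2] + ts * (b[2] - a[2]) - p[2])^2
  i <- which.min(d2)
  list(t = ts[i], dist = sqrt(d2[i]))
}

# Brute-force matching enumeration over the complete graph on n vertices:
# count subsets of edges with no shared vertex.
count_matchings_brute <- function(n) {
  edges <- utils::combn(n, 2)
  m <- ncol(edges)
  count <- 0L
  for (mask in 0:(2^m - 1)) {
    chosen <- which(bitwAnd(mask, 2^(0:(m - 1))) > 0)
    verts <- as.vector(edges[, chosen, drop = FALSE])
    if (!anyDuplicated(verts)) count <- count + 1L
  }
  count
}

# Uniform draw from the k-simplex.
random_simplex <- function(k) {
  x <- -log(runif(k))
  x / sum(x)
}

# Random valid peak list with shifts rounded to the 4-decimal file precision.
random_peak_list <- function(n = 10, with_intensity = FALSE, id = "random") {
  resno <- sort(sample(1:200, n))
  codes <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE)
  peak_list(data.frame(
    residue_number = resno,
    residue_code = codes,
    shift_H = round(runif(n, 6.5, 10.5), 4),
    shift_N = round(runif(n, 100, 135), 4),
    intensity = if (with_intensity) round(runif(n, 0.1, 9), 4) else NA_real_,
    stringsAsFactors = FALSE), spectrum_id = id)
}

# In-memory simulate -> project -> aggregate -> solve chain (no files).
simulate_and_solve <- function(populations, sigma_H = 0, sigma_N = 0,
                               seed = 1L, n_units = 3,
                               policy = "single_probe", probe_residue = 70L) {
  topo <- chain_topology(n_units)
  spec <- synthetic_spec(topo, populations,
                         sigma_H = sigma_H, sigma_N = sigma_N, seed = seed)
  sim <- simulate_chain_peaklists(spec)
  refs <- reference_pairs(sim$open_ref, sim$closed_ref)
  proj <- do.call(rbind, lapply(names(sim$units), function(u) {
    project_peaklist(sim$units[[u]], refs, unit_label = u)
  }))
  fr <- unit_open_fractions(proj, policy = policy,
                            probe_residue = probe_residue)
  solve_populations(enumerate_states(topo), fr$open_fraction)
}
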