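# Shared builders and independent oracles for the test suite.

toy_bout <- function(bout_id, individual_id, age, category = "tool",
                     typicality = "typical", atypical_mode = NA_character_,
                     subcategory = NA_character_) {
  data.frame(bout_id = bout_id, individual_id = individual_id,
             age_at_bout = age, category = category,
             subcategory = subcategory, typicality = typicality,
             atypical_mode = atypical_mode, stringsAsFactors = FALSE)
}

toy_individual <- function(individual_id, sex = "female",
                           parity = "primiparous",
                           maternal_id = paste0("M", individual_id),
                           observation_hours = 10, life_stage = "infant") {
  data.frame(individual_id = individual_id, sex = sex, parity = parity,
             maternal_id = maternal_id,
             observation_hours = observation_hours, life_stage = life_stage,
             stringsAsFactors = FALSE)
}

# Iteratively refined grid minimization of f over p coefficients: an
# implementation-independent oracle for the regression estimators.
grid_minimize <- function(f, center, width, n_zoom = 12, n_grid = 11) {
  p <- length(center)
  for (z in seq_len(n_zoom)) {
    grids <- lapply(seq_len(p), function(j)
      seq(center[j] - width[j], center[j] + width[j], length.out = n_grid))
    pts <- as.matrix(expand.grid(grids))
    vals <- apply(pts, 1, f)
    center <- pts[which.min(vals), ]
    width <- width * 2.2 / (n_grid - 1)   # shrink around the best point
  }
  unname(center)
}

# Exhaustive search over contiguous partitions of sorted values into k
# clusters: the brute-force oracle for kmeans_1d.
best_contiguous_partition <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  cuts <- utils::combn(n - 1, k - 1, simplify = FALSE)
  wcss_of <- function(cut) {
    bounds <- c(0, cut, n)
    sum(vapply(seq_len(k), function(m) {
      seg <- x[(bounds[m] + 1):bounds[m + 1]]
      sum((seg - mean(seg))^2)
    }, numeric(1)))
  }
  if (k == 1) return(sum((x - mean(x))^2))
  min(vapply(cuts, wcss_of, numeric(1)))
}

# Full-enumeration exact two-sided Mann-Whitney p-value over all
# choose(n1+n2, n1) labelings of the pooled (tie-free) sample.
enum_mw_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  combos <- utils::combn(n1 + n2, n1, simplify = FALSE)
  u_of <- function(ix) {
    r <- rank(pooled)
    sum(r[ix]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  us <- vapply(combos, u_of, numeric(1))
  pl <- mean(us <= u_obs)
  pg <- mean(us >= u_obs)
  min(1, 2 * min(pl, pg))
}

huber_rho_obj <- function(y, X, beta, s, c = 1.345) {
  u <- (y - drop(X %*% beta)) / s
  sum(ifelse(abs(u) <= c, u^2 / 2, c * abs(u) - c^2 / 2))
}
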