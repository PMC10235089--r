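# Shared fixtures and independent oracle implementations. Oracles here are
# deliberately written as plain nested loops / direct formulas, independent
# of the package's vectorized code paths.

# A cell map built from explicit coordinates/classes with constant filler
# descriptors (overridable per column).
toy_cell_map <- function(x, y, class, ..., width = 2048L, height = 2048L,
                         mpp = 0.5) {
  n <- length(x)
  df <- tibble::tibble(cell_id = seq_len(n), x = x, y = y, class = class)
  fill <- list(area = 200, perimeter = 55, eccentricity = 0.4,
               equiv_diameter = 16, solidity = 0.95,
               mean_R = 0.4, mean_G = 0.3, mean_B = 0.6)
  for (hc in phenotil::haralick_columns()) fill[[hc]] <- 0.5
  over <- list(...)
  for (nm in names(over)) fill[[nm]] <- over[[nm]]
  for (nm in names(fill)) df[[nm]] <- rep_len(fill[[nm]], n)
  phenotil::cell_map(df, microns_per_pixel = mpp, width = width,
                     height = height)
}

# A random cell map with independent random descriptors (no simulator
# machinery), for oracle-equivalence checks.
random_cell_map <- function(n = 200, seed = 1, width = 2048L) {
  set.seed(seed)
  df <- tibble::tibble(
    cell_id = seq_len(n),
    x = runif(n, 0, width - 1),
    y = runif(n, 0, width - 1),
    class = sample(c("TIL", "nonTIL"), n, replace = TRUE),
    area = runif(n, 50, 800),
    perimeter = runif(n, 20, 120),
    eccentricity = runif(n),
    equiv_diameter = runif(n, 8, 32),
    solidity = runif(n, 0.6, 1),
    mean_R = runif(n), mean_G = runif(n), mean_B = runif(n))
  for (hc in phenotil::haralick_columns()) df[[hc]] <- rnorm(n)
  phenotil::cell_map(df, microns_per_pixel = 0.5, width = width,
                     height = width)
}

# Brute-force re-enumeration of the 288 contextual features of one TIL:
# nested loops over cells and radii, direct statistic formulas.
oracle_til_features <- function(cm, til_id, radii = c(200, 400, 600),
                                mpp = 0.5) {
  i <- which(cm$cell_id == til_id)
  out <- c()
  gstat4 <- function(v) {
    if (length(v) == 0) return(c(0, 0, 0, 0))
    c(mean(v), if (length(v) > 1) sd(v) else 0, min(v), max(v))
  }
  gstat3 <- function(v) {
    if (length(v) == 0) return(c(0, 0, 0))
    c(mean(v), if (length(v) > 1) sd(v) else 0, max(v))
  }
  for (r in radii) {
    til_nb <- c(); non_nb <- c()
    for (j in seq_len(nrow(cm))) {
      if (j == i) next
      dij <- sqrt((cm$x[j] - cm$x[i])^2 + (cm$y[j] - cm$y[i])^2)
      if (dij <= r) {
        if (cm$class[j] == "TIL") til_nb <- c(til_nb, j)
        else non_nb <- c(non_nb, j)
      }
    }
    dist_to <- function(js) sapply(js, function(j)
      sqrt((cm$x[j] - cm$x[i])^2 + (cm$y[j] - cm$y[i])^2))
    n_t <- length(til_nb); n_n <- length(non_nb)
    disc <- pi * r^2 * mpp^2 / 1e6
    out <- c(out, n_t, n_n, n_t + n_n,
             if (n_t + n_n > 0) n_t / (n_t + n_n) else 0,
             n_t / disc, n_n / disc)
    out <- c(out, gstat4(if (n_t > 0) dist_to(til_nb) else numeric(0)),
             gstat4(if (n_n > 0) dist_to(non_nb) else numeric(0)))
    for (grp in list(til_nb, non_nb)) {
      for (m in c("area", "perimeter", "eccentricity", "equiv_diameter",
                  "solidity")) {
        out <- c(out, gstat4(cm[[m]][grp]))
      }
    }
    for (grp in list(til_nb, non_nb)) {
      for (ch in c("mean_R", "mean_G", "mean_B")) {
        out <- c(out, gstat3(cm[[ch]][grp]))
      }
    }
    for (grp in list(til_nb, non_nb)) {
      for (hc in phenotil::haralick_columns()) {
        out <- c(out, if (length(grp) > 0) mean(cm[[hc]][grp]) else 0)
      }
    }
  }
  unname(out)
}

# Object-level detection F1 at an IoU threshold, by exhaustive matching of
# each ground-truth object to its modal predicted label.
object_f1 <- function(pred, truth, iou = 0.5) {
  pl <- setdiff(unique(as.vector(pred)), 0)
  tl <- setdiff(unique(as.vector(truth)), 0)
  if (length(pl) == 0 || length(tl) == 0) return(0)
  tp <- 0
  for (t in tl) {
    tidx <- which(truth == t)
    cand <- table(pred[tidx])
    cand <- cand[names(cand) != "0"]
    if (length(cand) == 0) next
    best <- as.integer(names(cand)[which.max(cand)])
    pidx <- which(pred == best)
    i <- length(intersect(tidx, pidx))
    u <- length(union(tidx, pidx))
    if (i / u >= iou) tp <- tp + 1
  }
  prec <- tp / length(pl)
  rec <- tp / length(tl)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# Adjusted Rand index between two labelings (direct contingency formula).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# Union-find connected components at a linkage radius (oracle for the
# graph-based implementation).
uf_components <- function(x, y, radius) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) <= radius) {
      ri <- find(i)
      rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  as.integer(factor(roots))
}

# Small deterministic 8-patient survival table used for the hand-computed
# log-rank check.
eight_patient_survival <- function() {
  tibble::tibble(
    patient_id = paste0("P", 1:8),
    time = c(2, 4, 5, 7, 8, 10, 12, 14),
    event = c(1, 1, 0, 1, 1, 1, 0, 1))
}
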