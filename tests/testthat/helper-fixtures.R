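# shared fixtures, all built in code

# small aligned grid with a given value matrix
grid_of <- function(values, cell_size = 1000, name = "g") {
  raster_grid(as.matrix(values), origin_x = 0,
              origin_y = nrow(as.matrix(values)) * cell_size,
              cell_size = cell_size, name = name)
}

# perfectly separable design: label = (Altitude > 2800), one noise feature
separable_design <- function(n1 = 50, n0 = 500, seed = 42) {
  set.seed(seed)
  alt <- c(runif(n1, 3000, 5000), runif(n0, 1000, 2600))
  noise <- runif(n1 + n0)
  feats <- data.frame(Altitude = alt, Noise = noise)
  structure(list(features = feats, labels = c(rep(1L, n1), rep(0L, n0)),
                 presence = NULL, pseudo_absence = NULL,
                 ratio = n0 / n1, categorical_levels = list()),
            class = "training_design")
}

# small end-to-end fixture set: stack, truth, occurrences, design, model
small_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      stack <- generate_covariates(c(32, 32), 1000, seed = 11)
      truth <- true_suitability(stack)
      occ <- sample_occurrences(truth, 40, 20, seed = 12)
      lattice <- make_lattice(c(0, 0, 32000, 32000), 1000)
      pres <- extract_covariates(occ$presence, stack)
      abs <- sample_pseudo_absences(lattice, occ$presence, 5, seed = 13,
                                    grid = stack[[1]])
      abs <- extract_covariates(abs, stack)
      design <- assemble_design(pres, abs, stack)
      model <- fit_suitability(design, n_trees = 300, seed = 14)
      cache <<- list(stack = stack, truth = truth, occ = occ,
                     lattice = lattice, design = design, model = model)
    }
    cache
  }
})

# brute-force O(n^2) AUC oracle: pairwise concordance, ties half
auc_bruteforce <- function(labels, scores) {
  p <- scores[labels == 1]; n <- scores[labels == 0]
  tot <- 0
  for (a in p) for (b in n)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(p) * length(n))
}

# flood-fill connected-component oracle (8-connectivity)
flood_fill_components <- function(m, connectivity = 8) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  offs <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  for (start in which(m == 1)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      r <- (cur - 1) %% nr + 1; c <- (cur - 1) %/% nr + 1
      for (k in seq_len(nrow(offs))) {
        r2 <- r + offs[k, 1]; c2 <- c + offs[k, 2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            m[r2, c2] == 1 && lab[r2, c2] == 0L) {
          lab[r2, c2] <- nxt
          queue <- c(queue, (c2 - 1) * nr + r2)
        }
      }
    }
  }
  lab
}
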