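# Independent re-implementations of single operators, used as oracles for
# the compiled code via seed replay (both sides consume R's RNG stream in
# the documented draw order).

# hand implementation of the mutation boundary rules for one row
mutate_row_oracle <- function(w, free, pos, eps) {
  avail <- 1 - sum(w[!free])
  fp <- which(free)
  sel <- fp[pos]
  wold <- w[sel]
  wstar <- wold + eps
  if (wstar > avail) {
    w[fp] <- 0
    w[sel] <- avail
  } else {
    if (wstar < 0) wstar <- 0
    others <- avail - wold
    if (others <= 0) {
      w[fp] <- (avail - wstar) / (length(fp) - 1)
      w[sel] <- wstar
    } else {
      w[fp] <- w[fp] * (avail - wstar) / others
      w[sel] <- wstar
    }
  }
  w
}

# replay mutate()'s documented draw order for a whole matrix
mutate_oracle <- function(W, p_m, sigma, free_mask) {
  for (i in seq_len(nrow(W))) {
    if (runif(1) < p_m) {
      free <- free_mask[i, ] == 1
      m <- sum(free)
      if (m < 2) next
      pos <- min(floor(runif(1) * m) + 1, m)
      eps <- rnorm(1) * sigma
      W[i, ] <- mutate_row_oracle(W[i, ], free, pos, eps)
    }
  }
  W
}

# replay crossover()'s documented draw order (Fisher-Yates on free values)
crossover_oracle <- function(W, p_c, free_mask) {
  for (i in seq_len(nrow(W))) {
    if (runif(1) < p_c) {
      fp <- which(free_mask[i, ] == 1)
      m <- length(fp)
      if (m < 2) next
      vals <- W[i, fp]
      for (idx in m:2) {
        j <- min(floor(runif(1) * idx) + 1, idx)
        tmp <- vals[idx]; vals[idx] <- vals[j]; vals[j] <- tmp
      }
      W[i, fp] <- vals
    }
  }
  W
}

# replay blend_pair()'s documented draw order (one coin, then one beta)
blend_oracle <- function(B, C, p_b) {
  for (i in seq_len(nrow(B))) {
    if (runif(1) < p_b) {
      beta <- runif(1)
      bi <- B[i, ]; ci <- C[i, ]
      B[i, ] <- beta * bi + (1 - beta) * ci
      C[i, ] <- (1 - beta) * bi + beta * ci
    }
  }
  list(B = B, C = C)
}

# brute-force objective evaluation straight from its definition
fitness_oracle <- function(W, x_obs, n_bins) {
  Tn <- nrow(x_obs); N <- ncol(x_obs)
  xhat <- x_obs[1, ]
  total <- 0
  per_gene <- numeric(N)
  if (Tn > 1) {
    for (t in 2:Tn) {
      xhat <- as.numeric(W %*% xhat)
      for (i in 1:N) {
        B <- abs(back_transform(xhat[i], n_bins) -
                   back_transform(x_obs[t, i], n_bins))
        per_gene[i] <- per_gene[i] + B * abs(xhat[i] - x_obs[t, i])
      }
    }
  }
  list(total = sum(per_gene), per_gene = per_gene)
}

# a random valid weight matrix on a given adjacency structure
random_weights <- function(adjacency) {
  N <- nrow(adjacency)
  U <- matrix(runif(N * N), N, N)
  U[adjacency == 0] <- 0
  U / rowSums(U)
}

# small all-ones adjacency
full_adjacency <- function(N) matrix(1, N, N)
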