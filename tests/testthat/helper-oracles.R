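# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's vectorized code paths: plain loops over groups,
# samples and members.

brute_penalty <- function(s, V, epsilon) {
  total <- 0
  for (g in seq_len(nrow(V))) {
    for (n in seq_len(ncol(s))) {
      e <- 0
      for (j in seq_len(ncol(V))) {
        if (V[g, j] == 1) e <- e + s[j, n]^2
      }
      total <- total + sqrt(e + epsilon)
    }
  }
  total
}

brute_objective <- function(A, s, x, V, lambda, gamma, epsilon) {
  recon <- 0
  As <- A %*% s
  for (i in seq_len(nrow(x))) {
    for (n in seq_len(ncol(x))) recon <- recon + (As[i, n] - x[i, n])^2
  }
  recon + lambda * brute_penalty(s, V, epsilon) + gamma * sum(A^2)
}

# central finite differences of the objective
fd_grad_codes <- function(A, s, x, V, cfg, h = 1e-5) {
  out <- matrix(0, nrow(s), ncol(s))
  for (i in seq_len(nrow(s))) {
    for (n in seq_len(ncol(s))) {
      sp <- s; sp[i, n] <- sp[i, n] + h
      sm <- s; sm[i, n] <- sm[i, n] - h
      out[i, n] <- (tsc_objective(A, sp, x, V, cfg)$J -
                      tsc_objective(A, sm, x, V, cfg)$J) / (2 * h)
    }
  }
  out
}

fd_grad_dictionary <- function(A, s, x, V, cfg, h = 1e-5) {
  out <- matrix(0, nrow(A), ncol(A))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(ncol(A))) {
      Ap <- A; Ap[i, j] <- Ap[i, j] + h
      Am <- A; Am[i, j] <- Am[i, j] - h
      out[i, j] <- (tsc_objective(Ap, s, x, V, cfg)$J -
                      tsc_objective(Am, s, x, V, cfg)$J) / (2 * h)
    }
  }
  out
}

rel_err <- function(a, b) max(abs(a - b)) / max(max(abs(b)), 1e-12)

random_instance <- function(d, k, N, seed) {
  set.seed(seed)
  list(A = matrix(rnorm(d * k), d, k),
       s = matrix(rnorm(k * N), k, N),
       x = matrix(rnorm(d * N), d, N))
}

# a frame with hard-edged bright disks on a dark background
disk_frame <- function(h = 96, w = 96, centers, radius = 10,
                       fg = 0.9, bg = 0.05) {
  img <- matrix(bg, h, w)
  for (i in seq_len(nrow(centers))) {
    rr <- outer(seq_len(h) - centers[i, 1], rep(1, w))
    cc <- outer(rep(1, h), seq_len(w) - centers[i, 2])
    img[rr^2 + cc^2 <= radius^2] <- fg
  }
  img
}

easy_scene_config <- function(seed, n_frames = 24, n_cells = 6) {
  synth_image_config(n_frames = n_frames, n_cells_per_frame = n_cells,
                     seed = seed)
}
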