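## Cached heavy simulation runs, shared across test blocks.
##
## Problem sizes are the package's desk-scale study conditions: a 48-ring
## minicircle-only network evolved for 1e6 Langevin steps (topology
## conservation and thermostat checks), and a matched 32-ring MO/LB pair
## (6e5 steps each) for the curvature and marker-dynamics comparisons.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    t0 <- Sys.time()
    assign(key, force(expr), envir = .run_cache)
    message(sprintf("[%s built in %.1f min]", key,
                    as.numeric(difftime(Sys.time(), t0, units = "mins"))))
  }
  get(key, envir = .run_cache)
}

mo48_run <- function() {
  cached("mo48", {
    net <- build_mo(48, seed = 480)
    res <- run_protocol(net, sim_params(), equil_steps = 2e5,
                        prod_steps = 8e5, dump_every = 4000, seed = 481)
    list(net = net, res = res)
  })
}

pair32_runs <- function() {
  cached("pair32", {
    mo <- build_mo(32, seed = 320)
    moc <- compress_to_disk(mo, slit_gap = 4, ramp_steps = 5e4,
                            hold_steps = 2e4, seed = 321)
    lb <- suppressMessages(add_maxicircles(moc, mode = "LB", seed = 322))
    run <- function(net, seed) {
      run_protocol(net, sim_params(), equil_steps = 1.2e5,
                   prod_steps = 4.8e5, dump_every = 3000, seed = seed)
    }
    list(mo_net = moc, lb_net = lb,
         mo = run(moc, 323), lb = run(lb, 324))
  })
}

## moving-block bootstrap standard error of the mean of a (correlated)
## series
block_boot_se <- function(x, block = 20, n_boot = 500, seed = 1) {
  n <- length(x)
  nb <- ceiling(n / block)
  starts_all <- seq_len(n - block + 1)
  if (!exists(".Random.seed", globalenv())) stats::runif(1)
  old <- .Random.seed
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  means <- vapply(seq_len(n_boot), function(b) {
    s <- sample(starts_all, nb, replace = TRUE)
    mean(unlist(lapply(s, function(k) x[k:(k + block - 1)]))[seq_len(n)])
  }, 1.0)
  sd(means)
}

## COM trajectories of contiguous bead segments of a ring (sequence
## markers along a maxicircle)
segment_marker_coms <- function(frames, offset, ring_len, seg_len = 50,
                                n_seg = 6) {
  starts <- round(seq(1, ring_len - seg_len, length.out = n_seg))
  out <- array(NA_real_, c(length(frames), n_seg, 3))
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    for (s in seq_len(n_seg)) {
      rows <- offset + (starts[s]:(starts[s] + seg_len - 1))
      out[f, s, ] <- colMeans(fr[rows, , drop = FALSE])
    }
  }
  out
}
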