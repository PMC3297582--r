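# custom autonomous networks for oracle tests, plus a session-wide cache for
# the expensive default-parameter ensembles shared by several test files

# parameters whose drives are identically 1, so type-0 and type-3 reactions
# become autonomous (time-homogeneous) in custom test networks
flat_params <- function(...) {
  uptick_params(g_shape = c(floor0 = 1, rise_width = 1, floor_late = 1,
                            tau_fast = 1, tau_slow = 2, shoulder = 0.5),
                h_shape = c(floor0 = 1, rise_width = 1), ...)
}

make_custom_network <- function(species, reactions, stoich, mrna_idx,
                                params = default_params(), label = "custom",
                                tx_meta = rep(list(NULL), nrow(reactions))) {
  structure(list(species = species, reactions = reactions, stoich = stoich,
                 tx_meta = tx_meta,
                 mrna_idx = mrna_idx, oap_idx = NA_integer_,
                 strain = structure(list(rok_present = FALSE,
                                         spo0a_present = FALSE,
                                         site_mult = numeric(),
                                         n_promoters = length(mrna_idx),
                                         label = label),
                                    class = "uptick_strain"),
                 params = params, oap_fixed = NULL, t0 = params$t0),
            class = "uptick_network")
}

# immigration-death: M is born at constant rate `birth` (a transcription-type
# channel under flat drives, so births are logged as tx events) and decays at
# `death` per molecule
bd_network <- function(birth = 10, death = 1) {
  species <- c(M = 0L)
  reactions <- data.frame(
    label = c("birth", "death"), type = c(3L, 1L),
    const = c(birth, death), s1 = c(NA_integer_, 1L), s2 = NA_integer_)
  stoich <- rbind(1L, -1L)
  make_custom_network(species, reactions, stoich, mrna_idx = 1L,
                      params = flat_params(), label = "bd",
                      tx_meta = list(list(iA = integer(0), iRok = integer(0),
                                          iR = integer(0)), NULL))
}

# two-state telegraph promoter with transcription and decay
telegraph_network <- function(kon = 1, koff = 2, ktx = 8, kdeg = 1) {
  species <- c(Goff = 1L, Gon = 0L, M = 0L)
  reactions <- data.frame(
    label = c("on", "off", "tx", "deg"), type = rep(1L, 4),
    const = c(kon, koff, ktx, kdeg),
    s1 = c(1L, 2L, 2L, 3L), s2 = NA_integer_)
  stoich <- rbind(c(-1L, 1L, 0L), c(1L, -1L, 0L), c(0L, 0L, 1L),
                  c(0L, 0L, -1L))
  make_custom_network(species, reactions, stoich, mrna_idx = 3L,
                      label = "telegraph")
}

# exact stationary mRNA distribution of the telegraph model, by solving the
# truncated chemical master equation (independent of the simulator)
telegraph_stationary <- function(kon, koff, ktx, kdeg, N = 60) {
  ns <- 2L * (N + 1L)
  idx <- function(g, m) g * (N + 1L) + m + 1L
  Q <- matrix(0, ns, ns)
  add <- function(from, to, rate) {
    Q[from, to] <<- Q[from, to] + rate
    Q[from, from] <<- Q[from, from] - rate
  }
  for (m in 0:N) {
    add(idx(0, m), idx(1, m), kon)
    add(idx(1, m), idx(0, m), koff)
    if (m < N) add(idx(1, m), idx(1, m + 1), ktx)
    if (m > 0) {
      add(idx(0, m), idx(0, m - 1), kdeg * m)
      add(idx(1, m), idx(1, m - 1), kdeg * m)
    }
  }
  A <- t(Q)
  A[ns, ] <- 1
  pi <- solve(A, c(rep(0, ns - 1), 1))
  pmf <- pi[1:(N + 1)] + pi[(N + 2):ns]
  pmax(pmf, 0)
}

# minimal ensemble-shaped object for unit tests of the reduction functions
fake_ensemble <- function(tx_times_runs, t_end, times = NULL,
                          mrna_runs = NULL, label = "fake") {
  n_runs <- length(tx_times_runs[[1]])
  if (is.null(times)) times <- seq(0, t_end, by = 0.05)
  if (is.null(mrna_runs))
    mrna_runs <- list(matrix(0L, n_runs, length(times)))
  mean_counts <- do.call(cbind, lapply(mrna_runs, colMeans))
  colnames(mean_counts) <- paste0("mRNA_p", seq_along(mrna_runs))
  structure(list(times = times, mean_counts = mean_counts,
                 mrna_runs = mrna_runs,
                 tx_times = lapply(tx_times_runs, function(l)
                   unlist(l, use.names = FALSE)),
                 tx_times_runs = tx_times_runs,
                 n_runs = n_runs, base_seed = 1L, strain_label = label,
                 t_end = t_end,
                 mrna_species = paste0("mRNA_p", seq_along(mrna_runs))),
            class = "uptick_ensemble")
}

# session cache for expensive shared ensembles
.uptick_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .uptick_cache)) {
    assign(name, force(expr), envir = .uptick_cache)
  }
  get(name, envir = .uptick_cache)
}

# the default-parameter strain panel used by the acceptance and property
# tests: 1000-run ensembles, distinct seed blocks per strain
panel_strains <- function() {
  list(wt = uptick_strain("wt"),
       d_spo0A = uptick_strain("d_spo0A"),
       d_rok = uptick_strain("d_rok"),
       d_rok_d_spo0A = uptick_strain("d_rok_d_spo0A"),
       A123 = uptick_strain("A123"),
       A123_d_spo0A = uptick_strain("A123", spo0a_present = FALSE,
                                    label = "A123_d_spo0A"),
       A2 = uptick_strain("A2"))
}

strain_panel <- function(n_runs = 1000) {
  cached("strain_panel", {
    p <- default_params()
    strains <- panel_strains()
    ens <- lapply(seq_along(strains), function(i) {
      run_ensemble(build_network(strains[[i]], p), n_runs = n_runs,
                   t_end = 6, base_seed = 1L + i * 1000000L)
    })
    names(ens) <- names(strains)
    ens
  })
}

panel_curves <- function() {
  cached("panel_curves", lapply(strain_panel(), mean_rate_curve,
                                bin_width = 0.1))
}

dual_ensemble <- function() {
  cached("dual_ensemble", {
    p <- default_params()
    net <- build_network(uptick_strain("wt", n_promoters = 2), p)
    run_ensemble(net, n_runs = 2000, t_end = p$t0 + 2, base_seed = 42L)
  })
}
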