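# Shared fixtures and independent oracles for the test suite.

example_config <- function(seed = 1L, ...) {
  run_config(
    length_mass_coefficients = list(benthic = c(a = 0.0054, b = 2.83),
                                    emergence = c(a = 0.0054, b = 2.83)),
    pb_ratio = 13.63, rng_seed = seed, ...
  )
}

# Build a bilateral_measurements table from a list of per-individual
# replicate values: values[[id]] = list(L = c(...), R = c(...)).
make_table <- function(values, trait = "LFW", sex = "M") {
  rows <- lapply(names(values), function(id) {
    v <- values[[id]]
    data.frame(
      individual_id = id, sex = sex, trait = trait,
      side = rep(c("L", "R"), c(length(v$L), length(v$R))),
      replicate = c(seq_along(v$L), seq_along(v$R)),
      value = c(v$L, v$R), stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  M <- max(df$replicate)
  suppressMessages(bilat:::as_measurements(df, replicate_count = M))
}

# Naive double-loop ANOVA oracle for the balanced side x individual design,
# independent of the package's closed-form decomposition.
naive_anova_ss <- function(table, trait, sex) {
  df <- as.data.frame(table)
  df <- df[df$trait == trait & df$sex == sex, ]
  ids <- sort(unique(df$individual_id))
  sides <- c("L", "R")
  n <- length(ids)
  M <- max(df$replicate)
  gm <- mean(df$value)

  cell <- function(s, i) df$value[df$side == s & df$individual_id == i]
  ss_side <- 0
  for (s in sides) {
    ys <- df$value[df$side == s]
    ss_side <- ss_side + n * M * (mean(ys) - gm)^2
  }
  ss_ind <- 0
  for (i in ids) {
    yi <- df$value[df$individual_id == i]
    ss_ind <- ss_ind + 2 * M * (mean(yi) - gm)^2
  }
  ss_int <- 0
  ss_err <- 0
  for (s in sides) {
    for (i in ids) {
      ysi <- cell(s, i)
      ms <- mean(df$value[df$side == s])
      mi <- mean(df$value[df$individual_id == i])
      ss_int <- ss_int + M * (mean(ysi) - ms - mi + gm)^2
      for (y in ysi) ss_err <- ss_err + (y - mean(ysi))^2
    }
  }
  c(side = ss_side, individual = ss_ind, interaction = ss_int,
    error = ss_err)
}

# Random balanced measurement table for property tests.
random_table <- function(n, M, seed) {
  spec <- trait_sim_spec(n_individuals = n, replicates = M,
                         mean_size = 4, sd_size = 0.5, regime = "FA",
                         sd_d = 0.2, sd_me = 0.1, seed = seed)
  simulate_bilateral(spec)
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

tmpfile <- function(ext) tempfile(fileext = ext)
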