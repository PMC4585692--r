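# 32-bit arithmetic helpers on doubles (exact below 2^53), used by the
# counter-based seed derivation so results are identical across platforms.
.mod32 <- 4294967296
.xor32 <- function(x, y) {
  xh <- x %/% 65536; xl <- x %% 65536
  yh <- y %/% 65536; yl <- y %% 65536
  bitwXor(as.integer(xh), as.integer(yh)) * 65536 +
    bitwXor(as.integer(xl), as.integer(yl))
}
.mul32 <- function(x, y) {
  xh <- x %/% 65536; xl <- x %% 65536
  (((xh * y) %% 65536) * 65536 + xl * y) %% .mod32
}
# murmur3-style finalizer: bijective avalanche mix on [0, 2^32)
.mix32 <- function(z) {
  z <- .xor32(z, z %/% 65536)
  z <- .mul32(z, 2246822519)
  z <- .xor32(z, z %/% 8192)
  z <- .mul32(z, 3266489917)
  .xor32(z, z %/% 65536)
}

#' Derive per-realization seeds from a master seed
#'
#' Counter-based scheme: child seed `i` is the avalanche mix of the master
#' seed combined with the counter `i` (`mix(mix(master + C1) + i * C2)`,
#' 32-bit murmur-style finalizer, reported modulo `2^31`). Deterministic,
#' platform-independent, and collision-free within a list (duplicates, which
#' the mix makes astronomically rare, are re-mixed).
#'
#' @param master_seed Integer master seed.
#' @param reps Number of child seeds (>= 1).
#' @return An integer vector of `reps` distinct seeds in `[1, 2^31 - 1]`.
#' @export
derive_rep_seeds <- function(master_seed, reps) {
  if (!is.numeric(master_seed) || length(master_seed) != 1L ||
      !is.finite(master_seed) || master_seed != floor(master_seed))
    param_error("`master_seed` must be an integer")
  if (!is_count(reps, min = 1L)) param_error("`reps` must be >= 1")
  base <- .mix32((master_seed %% .mod32 + 2654435769) %% .mod32)
  seeds <- vapply(seq_len(reps), function(i) {
    s <- .mix32((base + .mul32(i, 2654435761)) %% .mod32) %% 2147483647 + 1
    s
  }, 0)
  while (anyDuplicated(seeds)) {
    d <- which(duplicated(seeds))
    seeds[d] <- .mix32((seeds[d] + 1) %% .mod32) %% 2147483647 + 1
  }
  as.integer(seeds)
}

# Full set of configuration keys understood by load_config()/the CLI, with
# their defaults. Topology keys describe either a generator or an edge-list
# file; the rest mirror decay_params().
.config_defaults <- function() {
  list(
    model = "er", nodes = 1000L, mean_degree = 10, links_per_node = 5L,
    triad_prob = 0, k = 10L, edges = "",
    p = 0.003, q = 0.99, r = 0.8, tau = 50L,
    th = 0.5, th_mu = NA_real_, th_sigma = NA_real_,
    p_link = 0, p_spawn = 0, spawn_links = NA_integer_,
    horizon = 100000L, extra_steps_after_crash = 200L,
    reps = 1L, seed = 1L, window = NA_integer_,
    out = "", log_level = "info"
  )
}

#' Load a flat key-value run configuration
#'
#' Reads a plain-text configuration file with one `key = value` pair per
#' line (`#` comments and blank lines ignored), merges it over the built-in
#' defaults, then applies `overrides` (e.g. command-line flags) with highest
#' precedence. Unknown keys are rejected with the list of valid keys;
#' values are coerced to the type of the corresponding default.
#'
#' @param path Path to the configuration file, or `NULL` for defaults only.
#' @param overrides Named list of values taking precedence over the file.
#' @return A named list of class `run_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- .config_defaults()
  file_vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) io_error("config file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    for (ln in lines) {
      kv <- regmatches(ln, regexec("^\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*?)\\s*$", ln))[[1L]]
      if (length(kv) != 3L)
        io_error("cannot parse config line: ", ln)
      file_vals[[kv[2L]]] <- kv[3L]
    }
  }
  apply_layer <- function(cfg, vals, origin) {
    for (key in names(vals)) {
      if (!key %in% names(cfg))
        param_error("unknown config key `", key, "` (", origin,
                    "); valid keys: ", paste(names(cfg), collapse = ", "))
      def <- cfg[[key]]
      val <- vals[[key]]
      cfg[[key]] <- if (is.character(def)) as.character(val)
      else if (is.integer(def)) {
        iv <- suppressWarnings(as.integer(val))
        if (is.na(iv) && !is.na(val)) param_error("config key `", key,
                                                  "`: expected integer, got ", val)
        iv
      } else {
        dv <- suppressWarnings(as.numeric(val))
        if (is.na(dv) && !is.na(val)) param_error("config key `", key,
                                                  "`: expected number, got ", val)
        dv
      }
    }
    cfg
  }
  cfg <- apply_layer(cfg, file_vals, "file")
  cfg <- apply_layer(cfg, overrides, "override")
  structure(cfg, class = "run_config")
}

#' Build decay_params from a run configuration
#'
#' Translates the flat configuration into a [decay_params()] object;
#' `th_mu`/`th_sigma`, when both set, select a Gaussian threshold spec over
#' the constant `th`.
#'
#' @param cfg A `run_config` from [load_config()].
#' @return A [decay_params()] object.
#' @export
config_params <- function(cfg) {
  threshold <- if (!is.na(cfg$th_mu) && !is.na(cfg$th_sigma))
    threshold_gaussian(cfg$th_mu, cfg$th_sigma)
  else threshold_constant(cfg$th)
  decay_params(
    p = cfg$p, q = cfg$q, r = cfg$r, tau = cfg$tau, threshold = threshold,
    p_link = cfg$p_link, p_spawn = cfg$p_spawn,
    spawn_links = if (is.na(cfg$spawn_links)) NULL else cfg$spawn_links,
    seed = cfg$seed, horizon = cfg$horizon,
    extra_steps_after_crash = cfg$extra_steps_after_crash
  )
}

#' Build a network from a run configuration
#'
#' Dispatches on `cfg$edges` (edge-list file) or `cfg$model`
#' (`"er"`, `"ba"`, `"ba-clustered"`, `"regular"`).
#'
#' @param cfg A `run_config`.
#' @return An `igraph` network.
#' @export
config_network <- function(cfg) {
  if (nzchar(cfg$edges)) return(read_edge_list(cfg$edges))
  switch(cfg$model,
    "er" = make_er(cfg$nodes, cfg$mean_degree, seed = cfg$seed),
    "ba" = make_ba(cfg$nodes, cfg$links_per_node, seed = cfg$seed),
    "ba-clustered" = make_ba_clustered(cfg$nodes, cfg$links_per_node,
                                       cfg$triad_prob, seed = cfg$seed),
    "regular" = make_regular(cfg$nodes, cfg$k, seed = cfg$seed),
    param_error("unknown model `", cfg$model,
                "`; expected er, ba, ba-clustered or regular")
  )
}
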