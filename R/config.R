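#' Pipeline configuration
#'
#' A flat `key = value` text format; `#` starts a comment. Unknown keys
#' are errors, which catches typos in rate constants. Values are coerced
#' to the declared type of each key.
#'
#' @param path Config file path.
#' @return A named list of class `pipeline_config` with defaults filled in.
#' @export
read_config <- function(path) {
  defaults <- pipeline_defaults()
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- defaults
  for (i in seq_along(lines)) {
    kv <- strsplit(lines[i], "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed config line: '", lines[i], "'")
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    if (!key %in% names(defaults)) stop("unknown config key: '", key, "'")
    cfg[[key]] <- if (is.numeric(defaults[[key]])) as.numeric(val) else val
  }
  validate_config(cfg)
}

#' @rdname read_config
#' @export
pipeline_defaults <- function() {
  list(mu_per_year = 2e-9, g_years = 5, bin_size = 100,
       pattern = "4+25*2+4+6", t_max = 15, em_iterations = 25,
       divergence_c = 10, block_length = 5e6, seed = 1,
       exclude_contigs = "", max_missing_fraction = 0.9)
}

validate_config <- function(cfg) {
  if (cfg$mu_per_year <= 0 || cfg$g_years <= 0) stop("mu and g must be positive")
  if (cfg$bin_size < 1) stop("bin_size must be >= 1")
  parse_pattern(cfg$pattern)  # errors on malformed patterns
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v) paste(format(v), collapse = ","),
                                character(1L)),
             sep = "=", collapse = ";")
  # small stable polynomial rolling hash, hex-encoded
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
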