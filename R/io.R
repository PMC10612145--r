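#' Parse a concentration with an optional unit suffix
#'
#' Accepts a bare number (molar) or a string with a `M`, `mM`, `uM`
#' (also `µM`), `nM`, `pM` or `fM` suffix; everything is normalized to
#' molar at the boundary so one unit convention holds internally.
#'
#' @param x Numeric or character scalar/vector.
#' @return Numeric, molar.
#' @export
parse_concentration <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, `µM` = 1e-6, nM = 1e-9,
             pM = 1e-12, fM = 1e-15)
  vapply(as.character(x), function(s) {
    s <- trimws(s)
    m <- regmatches(s, regexec("^([0-9.eE+-]+)\\s*([munµpf]?M)?$", s))[[1]]
    if (length(m) == 0L || m[2] == "")
      stop(sprintf("cannot parse concentration '%s'", s), call. = FALSE)
    unit <- if (m[3] == "") "M" else m[3]
    as.numeric(m[2]) * scale[[unit]]
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read a two-column instrument CSV
#'
#' Reads plate/spectrometer exports: `#`-prefixed header lines are
#' collected as metadata (`key: value` pairs where present), the rest is
#' a plain CSV.
#'
#' @param path File path.
#' @return data.frame with the file's columns; metadata in
#'   `attr(, "metadata")`.
#' @export
read_titration_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    body <- sub("^#\\s*", "", ml)
    if (grepl(":", body, fixed = TRUE)) {
      key <- trimws(sub(":.*$", "", body))
      val <- trimws(sub("^[^:]*:", "", body))
      meta[[key]] <- val
    }
  }
  d <- utils::read.csv(text = paste(lines[!grepl("^#", lines)],
                                    collapse = "\n"))
  attr(d, "metadata") <- meta
  d
}

#' Write a two-column instrument CSV
#'
#' Counterpart of [read_titration_csv()]; metadata entries are written
#' as `# key: value` header lines. Numbers are written at full double
#' precision so a write/read round trip is lossless.
#'
#' @param data data.frame to write.
#' @param path Output path.
#' @param metadata Named list of metadata entries.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(data, path, metadata = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(metadata))
    writeLines(sprintf("# %s: %s", key, metadata[[key]]), con)
  utils::write.csv(format(data, digits = 17, trim = TRUE, scientific = NA),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a speciation profile as tidy CSV
#'
#' Columns: `axis`, `species`, `fraction`, `free_zn_M`.
#'
#' @param profile A `speciation_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_speciation_csv <- function(profile, path) {
  stopifnot(inherits(profile, "speciation_profile"))
  write_titration_csv(as.data.frame(profile), path,
                      metadata = list(model = profile$model_name,
                                      axis_kind = profile$axis_kind))
}

expand_group <- function(g, label, errors, where) {
  if (is.null(g)) return(numeric(0))
  if (is.list(g) && !is.null(g$count)) {
    if (is.null(g$pkd)) {
      errors(sprintf("%s$groups$%s: missing 'pkd'", where, label))
      return(numeric(0))
    }
    return(rep(as.numeric(g$pkd), as.integer(g$count)))
  }
  as.numeric(unlist(g))
}

#' Load a model registry from a YAML or JSON configuration
#'
#' Reads protein, chelator and probe definitions, validates them against
#' the type invariants (every violation is reported with its field
#' path), and returns a registry. Protein steps may be given explicitly
#' (`pkd_steps`, tightest first) or as affinity groups
#' (`groups: {tight, moderate, weak}`, each either a value list or
#' `{count, pkd}`), which expand to repeated identical step constants.
#' Chelators accept `pkd` or `kd` (molar).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List with `proteins` (named list of [binding_model()]s, with
#'   optional `pka_prime`/`weak_release` attributes), `chelators`
#'   (named list of [chelator()]s) and `probes` (`$par`, `$znaf`).
#' @export
load_models <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else stop("config must be .yaml/.yml or .json", call. = FALSE)

  errs <- character(0)
  add_err <- function(msg) errs <<- c(errs, msg)

  proteins <- list()
  seen <- character(0)
  for (i in seq_along(raw$proteins)) {
    p <- raw$proteins[[i]]
    where <- sprintf("proteins[[%d]]", i)
    if (is.null(p$name)) { add_err(paste0(where, ": missing 'name'")); next }
    if (p$name %in% seen) {
      add_err(sprintf("%s: duplicate protein name '%s'", where, p$name))
      next
    }
    seen <- c(seen, p$name)
    steps <- if (!is.null(p$pkd_steps)) {
      as.numeric(unlist(p$pkd_steps))
    } else if (!is.null(p$groups)) {
      c(expand_group(p$groups$tight, "tight", add_err, where),
        expand_group(p$groups$moderate, "moderate", add_err, where),
        expand_group(p$groups$weak, "weak", add_err, where))
    } else {
      add_err(sprintf("%s (%s): missing 'pkd_steps' or 'groups'", where,
                      p$name))
      next
    }
    if (!is.null(p$n_sites) && length(steps) != p$n_sites) {
      add_err(sprintf("%s (%s): n_sites = %d but %d steps given", where,
                      p$name, p$n_sites, length(steps)))
      next
    }
    m <- tryCatch(binding_model(p$name, steps), error = function(e)
      { add_err(sprintf("%s (%s): %s", where, p$name, conditionMessage(e)))
        NULL })
    if (is.null(m)) next
    if (!is.null(p$pka_prime)) attr(m, "pka_prime") <- as.numeric(p$pka_prime)
    if (!is.null(p$weak_release)) attr(m, "weak_release") <- p$weak_release
    if (!is.null(p$groups))
      attr(m, "group_sizes") <- vapply(
        p$groups, function(g) length(expand_group(g, "", function(...) NULL,
                                                  "")), integer(1))
    proteins[[p$name]] <- m
  }

  chelators <- list()
  for (i in seq_along(raw$chelators)) {
    ch <- raw$chelators[[i]]
    where <- sprintf("chelators[[%d]]", i)
    if (is.null(ch$name)) { add_err(paste0(where, ": missing 'name'")); next }
    pkd <- if (!is.null(ch$pkd)) as.numeric(ch$pkd)
           else if (!is.null(ch$kd)) -log10(as.numeric(ch$kd))
           else { add_err(sprintf("%s (%s): missing 'pkd' or 'kd'", where,
                                  ch$name)); next }
    if (ch$name %in% names(chelators)) {
      add_err(sprintf("%s: duplicate chelator name '%s'", where, ch$name))
      next
    }
    chelators[[ch$name]] <- chelator(ch$name, pkd)
  }

  probes <- list()
  if (!is.null(raw$probes$par)) {
    pp <- raw$probes$par
    probes$par <- tryCatch(
      probe_2to1(pp$name %||% "PAR", as.numeric(pp$kd12),
                 as.numeric(pp$epsilon_492),
                 as.numeric(pp$path_length %||% 1)),
      error = function(e) { add_err(paste0("probes$par: ",
                                           conditionMessage(e))); NULL })
  }
  if (!is.null(raw$probes$znaf)) {
    pz <- raw$probes$znaf
    pkd <- if (!is.null(pz$pkd)) as.numeric(pz$pkd)
           else if (!is.null(pz$kd)) -log10(as.numeric(pz$kd))
           else { add_err("probes$znaf: missing 'pkd' or 'kd'"); NA_real_ }
    if (is.finite(pkd)) probes$znaf <- probe_1to1(pz$name %||% "ZnAF-2F", pkd)
  }

  if (length(errs))
    stop("model registry validation failed:\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  list(proteins = proteins, chelators = chelators, probes = probes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bundled fixture registry
#'
#' Loads the registry shipped with the package: ten metallothionein
#' stepwise models (animal, plant and bacterial), the competition
#' chelators (ATP, triphosphate, NTA, HEDTA, EDTA, TPEN) and both
#' probes (2:1 chromogenic, 1:1 fluorescent).
#'
#' @return See [load_models()].
#' @export
make_fixture_models <- function() {
  load_models(system.file("extdata", "mt_models.yaml", package = "znbuffer",
                          mustWork = TRUE))
}
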