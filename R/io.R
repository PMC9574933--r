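# Extended-XYZ trajectory I/O and the reproducible pipeline driver.

#' Write configurations to an extended-XYZ file
#'
#' One frame per configuration: a bead-count line, a comment line carrying
#' `box=<L> time=<t> shear_offset=<o>` and then per-bead columns
#' `species x y z vx vy vz molecule charge`. Floats are written at full
#' double precision so a write-read round trip is lossless.
#'
#' @param systems a `dpd_system`, a list of them, or a `dpd_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(systems, path) {
  systems <- as_system_list(systems)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in systems) {
    n <- nrow(s$positions)
    writeLines(as.character(n), con)
    writeLines(sprintf("box=%.17g time=%.17g shear_offset=%.17g",
                       s$box_edge, s$time, s$shear_offset), con)
    mol <- ifelse(is.na(s$molecule), 0L, s$molecule)
    lines <- sprintf("%s %.17g %.17g %.17g %.17g %.17g %.17g %d %.17g",
                     s$species, s$positions[, 1], s$positions[, 2],
                     s$positions[, 3], s$velocities[, 1],
                     s$velocities[, 2], s$velocities[, 3], mol, s$charge)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' Parses the format written by [write_trajectory()]. Frames are handed to
#' `callback` one at a time when it is supplied (streaming); otherwise all
#' frames are returned as a list.
#'
#' @param path input file.
#' @param callback optional `function(system, frame_index)`; when given,
#'   frames are not accumulated.
#' @return list of [dpd_system()] frames (or `invisible(NULL)` in
#'   streaming mode).
#' @export
read_trajectory <- function(path, callback = NULL) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(lines[i]))
    if (is.na(n)) stop("expected a bead count at line ", i, call. = FALSE)
    frame <- frame + 1L
    if (i + 1L > length(lines)) {
      stop("truncated frame ", frame, " at line ", i, call. = FALSE)
    }
    meta <- lines[i + 1L]
    kv <- regmatches(meta, gregexpr("[A-Za-z_]+=[-+0-9.eE]+", meta))[[1]]
    vals <- stats::setNames(
      as.numeric(sub("^[^=]+=", "", kv)), sub("=.*$", "", kv))
    if (!("box" %in% names(vals))) {
      stop("frame ", frame, ": missing box metadata on line ", i + 1L,
           call. = FALSE)
    }
    rows <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(rows, "[ \t]+")
    m <- t(vapply(parts, function(p) as.numeric(p[2:9]), numeric(8)))
    spec <- vapply(parts, `[[`, character(1), 1L)
    mol <- as.integer(m[, 7])
    sys <- dpd_system(
      positions = m[, 1:3, drop = FALSE],
      velocities = m[, 4:6, drop = FALSE],
      species = spec,
      molecule = ifelse(mol == 0L, NA_integer_, mol),
      charge = m[, 8],
      box_edge = vals[["box"]],
      shear_offset = if ("shear_offset" %in% names(vals)) {
        vals[["shear_offset"]]
      } else 0,
      time = if ("time" %in% names(vals)) vals[["time"]] else 0)
    if (is.null(callback)) out[[frame]] <- sys else callback(sys, frame)
    i <- i + 2L + n
  }
  if (is.null(callback)) out else invisible(NULL)
}

#' Run a build/fixture -> simulate -> analyze pipeline
#'
#' Executes the stages named in `config` and writes every product plus a
#' manifest (seeds, effective settings, file checksums) under `out_dir`.
#' Re-running the same config and seed reproduces the outputs bitwise
#' (modulo the manifest timestamp).
#'
#' Config fields: `seed`; exactly one of `fixture` (a list with `kind` in
#' micellar/lamellar/hexagonal plus the generator arguments) or `build`
#' (list with `L`, `weight_percent`, `n`); optional `simulate` (list with
#' `n_steps`, `snapshot_stride`, `shear_rate`, `electrostatics`); optional
#' `analyses` (character subset of "micelles", "lamellar", "hexagonal",
#' "phase").
#'
#' @param config pipeline configuration list.
#' @param out_dir output directory (created).
#' @param force_field force field for every stage.
#' @return the manifest list, invisibly; written as `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir,
                         force_field = load_force_field()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  manifest <- list(seed = seed, config = config, outputs = list(),
                   stages = character(0))
  ff <- force_field
  sys <- NULL
  if (!is.null(config$fixture)) {
    fx <- config$fixture
    sys <- switch(fx$kind,
      micellar = make_micelle_field(
        sizes = fx$sizes, L = fx$L, target_rg = fx$target_rg %||% 2,
        n_ethoxy = fx$n_ethoxy %||% 0,
        noise_sigma = fx$noise_sigma %||% 0, seed = seed,
        force_field = ff),
      lamellar = make_lamellar(
        L = fx$L, kappa_vec = fx$kappa_vec %||% c(5, 0, 0),
        n_ethoxy = fx$n_ethoxy %||% 0, bridge = isTRUE(fx$bridge),
        noise_sigma = fx$noise_sigma %||% 0, seed = seed,
        force_field = ff),
      hexagonal = make_hexagonal(
        L = fx$L, a = fx$a %||% c(10, 0), b = fx$b %||% c(4, 8),
        n_ethoxy = fx$n_ethoxy %||% 0,
        noise_sigma = fx$noise_sigma %||% 0, seed = seed,
        force_field = ff),
      stop("unknown fixture kind: ", fx$kind, call. = FALSE))
    manifest$stages <- c(manifest$stages, "fixture")
  } else if (!is.null(config$build)) {
    b <- config$build
    topo <- build_slens(b$n %||% 0, ff)
    comp <- composition_from_weight_percent(b$L, b$weight_percent, topo,
                                            force_field = ff)
    sys <- random_initial_configuration(comp, seed = seed)
    manifest$stages <- c(manifest$stages, "build")
  } else {
    stop("config must contain a `fixture` or `build` stage", call. = FALSE)
  }
  if (!is.null(config$simulate)) {
    sm <- config$simulate
    traj <- run_dpd(sys, ff, n_steps = sm$n_steps %||% 1000L, seed = seed,
                    snapshot_stride = sm$snapshot_stride %||% 0L,
                    shear_rate = sm$shear_rate %||% 0,
                    electrostatics = sm$electrostatics)
    sys2 <- traj$system
    attr(sys2, "ground_truth") <- attr(sys, "ground_truth")
    sys <- sys2
    manifest$stages <- c(manifest$stages, "simulate")
  }
  traj_path <- file.path(out_dir, "final.extxyz")
  write_trajectory(sys, traj_path)
  manifest$outputs$trajectory <- basename(traj_path)
  results <- list()
  for (an in config$analyses %||% character(0)) {
    res <- switch(an,
      micelles = {
        ms <- find_micelles(sys)
        list(n_micelles = length(ms$sizes), sizes = ms$sizes,
             n_agg = mean(ms$sizes), r_gyration = ms$r_gyration)
      },
      lamellar = {
        lm <- try(measure_lamellar(sys), silent = TRUE)
        if (inherits(lm, "try-error")) {
          list(error = attr(lm, "condition")$message)
        } else {
          list(d = lm$d, theta = lm$theta, kappa = lm$kappa)
        }
      },
      hexagonal = {
        hx <- try(measure_hexagonal(sys), silent = TRUE)
        if (inherits(hx, "try-error")) {
          list(error = attr(hx, "condition")$message)
        } else {
          list(r_s = hx$r_s, lengths = hx$lengths,
               orientation = hx$orientation)
        }
      },
      phase = {
        pc <- classify_phase(sys)
        list(label = pc$label)
      },
      stop("unknown analysis: ", an, call. = FALSE))
    results[[an]] <- res
  }
  if (length(results)) {
    res_path <- file.path(out_dir, "analysis.json")
    jsonlite::write_json(results, res_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    manifest$outputs$analysis <- basename(res_path)
  }
  files <- file.path(out_dir, unlist(manifest$outputs))
  manifest$checksums <- as.list(stats::setNames(
    unname(tools::md5sum(files)), basename(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}
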