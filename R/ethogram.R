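#' @title Ethogram configuration
#' @name ethogram_config
#' @description
#' An ethogram configuration declares the behavior catalogue used for coding
#' (one behavior is the fallback "default", e.g. standing/walking), the
#' coordinate-zone rules that map keypoint positions to behaviors, the anchor
#' bodyparts whose validity defines whether the animal is in view at all, the
#' video frame rate and the likelihood threshold (p-cutoff) used to condition
#' keypoint estimates.
NULL

#' Sentinel label for unobserved time
#'
#' Label assigned to frames/seconds where the subject could not be coded:
#' either genuinely out of camera view or unlabeled by the tracking model.
#' It is always part of the label set of a [behavior_sequence()].
#'
#' @export
OUT_OF_VIEW <- "Out of view"

#' Declare a behavior
#'
#' @param name Behavior label (unique within a config).
#' @param is_default `TRUE` for the fallback behavior assigned when the
#'   subject is in view but no zone rule matches. Exactly one behavior per
#'   configuration may be the default.
#' @param min_duration_s Minimum bout duration in seconds; maximal runs
#'   shorter than this are relabeled to the default behavior by
#'   [enforce_min_duration()]. Use 0 for no constraint.
#' @return A one-row data frame describing the behavior.
#' @export
behavior <- function(name, is_default = FALSE, min_duration_s = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (min_duration_s < 0) stop("min_duration_s must be >= 0 for behavior '", name, "'")
  data.frame(name = name, is_default = isTRUE(is_default),
             min_duration_s = as.numeric(min_duration_s))
}

#' Declare a coordinate-zone rule
#'
#' A rule matches a frame when every constrained bodypart has a valid
#' (likelihood-conditioned, non-missing) estimate lying inside its axis-aligned
#' pixel box. Pixel coordinates have the origin at the top-left of the frame
#' with y increasing downward, following the pose-CSV convention.
#'
#' @param behavior Name of the behavior this rule codes.
#' @param priority Integer rank; when several rules match one frame the rule
#'   with the lowest priority number wins. Unique within a config.
#' @param constraints Data frame with columns `bodypart`, `x_min`, `x_max`,
#'   `y_min`, `y_max` (pixels); at least one row.
#' @return A `zone_rule` list.
#' @export
zone_rule <- function(behavior, priority, constraints) {
  constraints <- as.data.frame(constraints)
  need <- c("bodypart", "x_min", "x_max", "y_min", "y_max")
  if (!all(need %in% names(constraints)) || nrow(constraints) == 0L)
    stop("zone rule for '", behavior, "' needs a non-empty constraint table ",
         "with columns ", paste(need, collapse = ", "))
  if (any(constraints$x_min > constraints$x_max) ||
      any(constraints$y_min > constraints$y_max))
    stop("zone rule for '", behavior, "': box with min > max")
  constraints <- constraints[, need]
  constraints$bodypart <- as.character(constraints$bodypart)
  for (cc in need[-1]) constraints[[cc]] <- as.numeric(constraints[[cc]])
  structure(list(behavior = as.character(behavior),
                 priority = as.integer(priority),
                 constraints = constraints),
            class = "zone_rule")
}

#' Assemble and validate an ethogram configuration
#'
#' @param behaviors Data frame of behaviors, usually `rbind()` of
#'   [behavior()] rows.
#' @param zone_rules List of [zone_rule()] objects (may be empty: the
#'   classifier then emits only the default behavior and out-of-view).
#' @param bodyparts Character vector of declared keypoint names.
#' @param anchor_bodyparts Bodyparts whose joint invalidity marks a frame as
#'   out of view; must be a subset of `bodyparts`.
#' @param fps Video frame rate (frames/second), > 0.
#' @param p_cutoff Likelihood threshold in \[0, 1\]; estimates with
#'   likelihood below it are treated as missing.
#' @param frame_size Named numeric `c(width =, height =)` in pixels.
#' @param geometry Optional simulator geometry: named list mapping each
#'   behavior to a named list of bodypart `c(x, y)` positions.
#' @param sway Optional simulator sway kinematics:
#'   `list(amplitude_px =, period_s =, bodyparts =)`.
#' @return A validated `ethogram_config` object.
#' @seealso [read_ethogram_config()], [default_ethogram_config()]
#' @export
ethogram_config <- function(behaviors, zone_rules = list(),
                            bodyparts, anchor_bodyparts,
                            fps = 25, p_cutoff = 0.5,
                            frame_size = c(width = 1920, height = 1080),
                            geometry = NULL, sway = NULL) {
  cfg <- structure(list(
    behaviors = as.data.frame(behaviors),
    zone_rules = zone_rules,
    bodyparts = as.character(bodyparts),
    anchor_bodyparts = as.character(anchor_bodyparts),
    fps = as.numeric(fps),
    p_cutoff = as.numeric(p_cutoff),
    frame_size = c(width = as.numeric(frame_size[["width"]]),
                   height = as.numeric(frame_size[["height"]])),
    geometry = geometry,
    sway = sway
  ), class = "ethogram_config")
  # canonical order: rules sorted by priority
  pr <- vapply(cfg$zone_rules, function(r) r$priority, integer(1))
  cfg$zone_rules <- cfg$zone_rules[order(pr)]
  validate_ethogram_config(cfg)
  cfg
}

#' Validate an ethogram configuration
#'
#' Checks every structural invariant and raises a distinct error naming the
#' offending entry: exactly one default behavior, unique behavior names,
#' non-negative minimum durations, unique rule priorities, rules referencing
#' only declared behaviors and bodyparts, no rule on the default behavior,
#' fps > 0 and p-cutoff in \[0, 1\].
#'
#' @param config An `ethogram_config`.
#' @return `config`, invisibly, if valid.
#' @export
validate_ethogram_config <- function(config) {
  b <- config$behaviors
  if (nrow(b) == 0L) stop("config declares no behaviors")
  if (anyDuplicated(b$name))
    stop("duplicate behavior name: '", b$name[duplicated(b$name)][1], "'")
  ndef <- sum(b$is_default)
  if (ndef != 1L)
    stop("config must have exactly one default behavior, found ", ndef,
         if (ndef > 1) paste0(" (", paste(b$name[b$is_default], collapse = ", "), ")"))
  if (any(b$min_duration_s < 0))
    stop("negative min_duration_s for behavior '",
         b$name[b$min_duration_s < 0][1], "'")
  default <- b$name[b$is_default]

  pr <- vapply(config$zone_rules, function(r) r$priority, integer(1))
  if (anyDuplicated(pr))
    stop("duplicate zone-rule priority: ", pr[duplicated(pr)][1])
  for (r in config$zone_rules) {
    if (!r$behavior %in% b$name)
      stop("zone rule references undeclared behavior '", r$behavior, "'")
    if (r$behavior == default)
      stop("default behavior '", default, "' must not have a zone rule")
    bad <- setdiff(r$constraints$bodypart, config$bodyparts)
    if (length(bad))
      stop("zone rule for '", r$behavior,
           "' references undeclared bodypart '", bad[1], "'")
  }
  bad_anchor <- setdiff(config$anchor_bodyparts, config$bodyparts)
  if (length(bad_anchor))
    stop("anchor bodypart '", bad_anchor[1], "' is not a declared bodypart")
  if (length(config$anchor_bodyparts) == 0L)
    stop("config needs at least one anchor bodypart")
  if (!is.finite(config$fps) || config$fps <= 0) stop("fps must be > 0")
  if (is.na(config$p_cutoff) || config$p_cutoff < 0 || config$p_cutoff > 1)
    stop("p_cutoff must lie in [0, 1]")
  if (!is.null(config$geometry)) {
    for (bn in names(config$geometry)) {
      if (!bn %in% b$name)
        stop("geometry entry for undeclared behavior '", bn, "'")
      bad <- setdiff(names(config$geometry[[bn]]), config$bodyparts)
      if (length(bad))
        stop("geometry for '", bn, "' names undeclared bodypart '", bad[1], "'")
    }
  }
  invisible(config)
}

#' @export
print.ethogram_config <- function(x, ...) {
  cat("<ethogram_config>\n")
  cat("  behaviors: ", paste0(x$behaviors$name,
      ifelse(x$behaviors$is_default, "*", ""), collapse = ", "),
      "  (* = default)\n", sep = "")
  cat("  zone rules:", length(x$zone_rules),
      " | bodyparts:", paste(x$bodyparts, collapse = ", "), "\n")
  cat("  anchors:", paste(x$anchor_bodyparts, collapse = ", "),
      "| fps:", x$fps, "| p-cutoff:", x$p_cutoff, "\n")
  invisible(x)
}

#' Default behavior name of a config
#' @param config An `ethogram_config`.
#' @return The name of the default behavior.
#' @export
default_behavior <- function(config) {
  config$behaviors$name[config$behaviors$is_default]
}

#' Full label set of a config
#' @param config An `ethogram_config`.
#' @return Behavior names plus the [OUT_OF_VIEW] sentinel, in a fixed order:
#'   zone-ruled behaviors by priority, remaining behaviors in declaration
#'   order, the default last before `OUT_OF_VIEW`.
#' @export
label_set <- function(config) c(config$behaviors$name, OUT_OF_VIEW)

# Tie-break rank used by second-level aggregation: zone rules by priority,
# then ruleless non-default behaviors in declaration order, then the default,
# then OUT_OF_VIEW (which loses every tie).
tie_rank <- function(config) {
  nm <- config$behaviors$name
  rk <- rep(NA_real_, length(nm))
  names(rk) <- nm
  for (r in config$zone_rules) rk[r$behavior] <- r$priority
  maxpr <- if (length(config$zone_rules)) max(vapply(config$zone_rules,
      function(r) r$priority, integer(1))) else 0
  ruleless <- is.na(rk) & !config$behaviors$is_default
  rk[ruleless] <- maxpr + seq_len(sum(ruleless))
  rk[config$behaviors$is_default] <- maxpr + sum(ruleless) + 1
  c(rk, structure(Inf, names = OUT_OF_VIEW))
}

#' Read an ethogram configuration from YAML
#'
#' The file layout mirrors the constructor arguments; see the shipped default
#' at `system.file("extdata", "default_config.yaml", package = "ethonight")`
#' for a complete annotated example.
#'
#' @param path Path to a YAML config file.
#' @return A validated `ethogram_config`.
#' @export
read_ethogram_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  behaviors <- do.call(rbind, lapply(y$behaviors, function(b)
    behavior(b$name, isTRUE(b$default),
             if (is.null(b$min_duration_s)) 0 else b$min_duration_s)))
  rules <- lapply(y$zone_rules, function(r)
    zone_rule(r$behavior, r$priority,
              do.call(rbind, lapply(r$constraints, as.data.frame))))
  geometry <- if (!is.null(y$geometry))
    lapply(y$geometry, function(g) lapply(g, as.numeric))
  sway <- y$sway
  ethogram_config(
    behaviors = behaviors, zone_rules = rules,
    bodyparts = unlist(y$bodyparts),
    anchor_bodyparts = unlist(y$anchor_bodyparts),
    fps = y$fps, p_cutoff = y$p_cutoff,
    frame_size = c(width = y$frame_size$width, height = y$frame_size$height),
    geometry = geometry, sway = sway)
}

#' Write an ethogram configuration to YAML
#'
#' Inverse of [read_ethogram_config()]: `read_ethogram_config(write_ethogram_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param config An `ethogram_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ethogram_config <- function(config, path) {
  y <- list(
    fps = config$fps,
    p_cutoff = config$p_cutoff,
    frame_size = list(width = unname(config$frame_size[["width"]]),
                      height = unname(config$frame_size[["height"]])),
    bodyparts = as.list(config$bodyparts),
    anchor_bodyparts = as.list(config$anchor_bodyparts),
    behaviors = lapply(seq_len(nrow(config$behaviors)), function(i) {
      b <- config$behaviors[i, ]
      out <- list(name = b$name)
      if (b$is_default) out$default <- TRUE
      if (b$min_duration_s > 0) out$min_duration_s <- b$min_duration_s
      out
    }),
    zone_rules = lapply(config$zone_rules, function(r) list(
      behavior = r$behavior, priority = r$priority,
      constraints = lapply(seq_len(nrow(r$constraints)), function(i)
        as.list(r$constraints[i, ]))))
  )
  if (!is.null(config$geometry))
    y$geometry <- lapply(config$geometry, function(g) lapply(g, as.numeric))
  if (!is.null(config$sway)) y$sway <- config$sway
  yaml::write_yaml(y, path)
  invisible(path)
}

#' The shipped default configuration
#'
#' A five-behavior nocturnal elephant ethogram (standing as default, lying
#' down, foraging, hay-net, drinking, plus swaying with a 5-s minimum bout)
#' with illustrative zone boxes on a 1920 x 1080 frame at 25 FPS,
#' p-cutoff 0.5, and simulator geometry placing each behavior's constrained
#' bodyparts inside its own zone. Swaying carries no zone rule: it is not
#' coded by position but detected from trunk-root displacement (see
#' [detect_sway_bouts()]).
#'
#' @return A validated `ethogram_config`.
#' @export
default_ethogram_config <- function() {
  read_ethogram_config(system.file("extdata", "default_config.yaml",
                                   package = "ethonight", mustWork = TRUE))
}
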