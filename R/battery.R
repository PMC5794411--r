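#' Construct a test battery
#'
#' A battery is the instrument the Eta-Mu model scores against: an ordered
#' set of named tests, each with a visuoperceptive (VP) and a
#' visuomotor-coordination (VMC) recruitment weight, expressed as percents
#' that sum to 100 for every test. The battery-level mean weights (76/24 for
#' the default battery) are derived quantities, never hard-coded constants,
#' so any battery with valid per-test weights is accepted.
#'
#' @param tests A data frame with columns `name`, `vp_weight`, `vmc_weight`.
#' @param label Free-text battery name.
#' @param validate If `TRUE` (default), invalid batteries raise an error
#'   listing every violation; see [validate_battery()].
#'
#' @return A tibble of class `etamu_battery` with columns `name`,
#'   `vp_weight`, `vmc_weight` and a `label` attribute.
#' @seealso [default_battery()], [validate_battery()], [mean_weights()]
#' @export
#' @examples
#' battery(
#'   data.frame(name = c("copy", "trace"), vp_weight = c(80, 20),
#'              vmc_weight = c(20, 80)),
#'   label = "toy"
#' )
battery <- function(tests, label = "custom battery", validate = TRUE) {
  stopifnot(is.data.frame(tests))
  missing_cols <- setdiff(c("name", "vp_weight", "vmc_weight"), names(tests))
  if (length(missing_cols) > 0) {
    abort(paste0("`tests` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- as_tibble(tests[, c("name", "vp_weight", "vmc_weight")])
  out$name <- as.character(out$name)
  out$vp_weight <- as.numeric(out$vp_weight)
  out$vmc_weight <- as.numeric(out$vmc_weight)
  attr(out, "label") <- as.character(label)[1]
  class(out) <- c("etamu_battery", class(out))
  if (validate) {
    violations <- validate_battery(out)
    if (length(violations) > 0) {
      abort(paste0("invalid battery:\n",
                   paste0("- ", violations, collapse = "\n")))
    }
  }
  out
}

#' The default ten-test battery
#'
#' Five instruments contribute ten scored tests: three BVS-Corsi visuospatial
#' working-memory tests and the Developmental Eye Movement ratio are treated
#' as purely visuoperceptive (100/0); handwriting quality and velocity (BHK)
#' load mainly on motor coordination (30/70); bell-cancellation velocity and
#' accuracy (TCM) are 80/20; Rey-Osterrieth complex-figure copy and memory
#' are 70/30. The mean recruitment over the full battery is 76% VP / 24% VMC.
#'
#' @return An `etamu_battery` with 10 tests.
#' @export
#' @examples
#' mean_weights(default_battery())
default_battery <- function() {
  battery(
    tibble(
      name = c("corsi_visual", "corsi_simultaneous", "corsi_sequential",
               "bhk_quality", "bhk_velocity",
               "tcm_velocity", "tcm_accuracy",
               "rocf_copy", "rocf_memory",
               "dem_ratio"),
      vp_weight  = c(100, 100, 100, 30, 30, 80, 80, 70, 70, 100),
      vmc_weight = c(0, 0, 0, 70, 70, 20, 20, 30, 30, 0)
    ),
    label = "default 10-test VP/VMC battery"
  )
}

#' Validate a battery
#'
#' Checks every battery invariant and reports violations instead of raising:
#' at least one test, nonempty unique names, weights within 0--100, and
#' `vp_weight + vmc_weight == 100` for every test.
#'
#' @param battery An [battery()] object or data frame with the same columns.
#' @return A character vector of violation descriptions, each naming the
#'   offending test and rule; empty when the battery is valid.
#' @export
validate_battery <- function(battery) {
  violations <- character()
  if (!is.data.frame(battery) ||
      !all(c("name", "vp_weight", "vmc_weight") %in% names(battery))) {
    return("not a battery: needs columns name, vp_weight, vmc_weight")
  }
  if (nrow(battery) == 0) {
    return("battery has no tests (at least 1 required)")
  }
  nm <- as.character(battery$name)
  if (anyNA(nm) || any(!nzchar(nm))) {
    violations <- c(violations, "test with empty name")
  }
  dup <- unique(nm[duplicated(nm)])
  if (length(dup) > 0) {
    violations <- c(violations,
                    paste0("duplicate test name: ", dup))
  }
  for (i in seq_len(nrow(battery))) {
    vp <- battery$vp_weight[i]
    vmc <- battery$vmc_weight[i]
    id <- if (!is.na(nm[i]) && nzchar(nm[i])) nm[i] else paste0("row ", i)
    if (is.na(vp) || is.na(vmc)) {
      violations <- c(violations, paste0("test ", id, ": missing weight"))
      next
    }
    if (vp < 0 || vp > 100 || vmc < 0 || vmc > 100) {
      violations <- c(violations,
                      paste0("test ", id, ": weights must lie in [0, 100]"))
    }
    if (abs(vp + vmc - 100) > 1e-9) {
      violations <- c(violations,
                      paste0("test ", id, ": vp_weight + vmc_weight must equal ",
                             "100 (got ", vp + vmc, ")"))
    }
  }
  violations
}

#' Mean recruitment weights over an administered subset
#'
#' The expected-value baselines of the model use the arithmetic mean VP and
#' VMC weight over the tests a subject actually completed. For the full
#' default battery this is 76/24; for an incomplete session (e.g. a child
#' refusing one instrument) the means are recomputed over the administered
#' subset, which is what makes expected indices comparable across complete
#' and incomplete sessions.
#'
#' @param battery An [battery()] object.
#' @param administered Character vector of administered test names, or `NULL`
#'   (default) for the full battery.
#' @return A one-row tibble with `n_tests`, `mean_vp`, `mean_vmc`;
#'   `mean_vp + mean_vmc == 100` always.
#' @export
#' @examples
#' mean_weights(default_battery())                      # 76 / 24
#' mean_weights(default_battery(), c("dem_ratio"))      # 100 / 0
mean_weights <- function(battery, administered = NULL) {
  stopifnot(is.data.frame(battery))
  if (is.null(administered)) {
    sub <- battery
  } else {
    administered <- as.character(administered)
    if (length(administered) == 0) {
      abort("`administered` must name at least one test")
    }
    unknown <- setdiff(administered, battery$name)
    if (length(unknown) > 0) {
      abort(paste0("test(s) not in battery: ",
                   paste(unknown, collapse = ", ")))
    }
    sub <- battery[battery$name %in% administered, ]
  }
  tibble(
    n_tests = nrow(sub),
    mean_vp = mean(sub$vp_weight),
    mean_vmc = mean(sub$vmc_weight)
  )
}

#' Read and write battery configuration files
#'
#' Batteries are stored as JSON documents
#' `{"label": ..., "tests": [{"name": ..., "vp_weight": ...,
#' "vmc_weight": ...}, ...]}`. The default battery ships with the package as
#' `system.file("extdata", "battery_default.json", package = "etamu")`.
#'
#' @param path File path.
#' @param battery An [battery()] object.
#' @param validate Passed on to [battery()] on read.
#' @return `read_battery()` returns an `etamu_battery`; `write_battery()`
#'   returns `path` invisibly.
#' @export
read_battery <- function(path, validate = TRUE) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(doc$tests)) {
    abort(paste0("battery file ", path, " has no `tests` field"))
  }
  battery(as.data.frame(doc$tests),
          label = doc$label %||% "unnamed battery",
          validate = validate)
}

#' @rdname read_battery
#' @export
write_battery <- function(battery, path) {
  stopifnot(is.data.frame(battery))
  doc <- list(
    label = attr(battery, "label") %||% "unnamed battery",
    tests = data.frame(name = battery$name,
                       vp_weight = battery$vp_weight,
                       vmc_weight = battery$vmc_weight)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.etamu_battery <- function(x, ...) {
  mw <- mean_weights(x)
  cat(sprintf("<etamu_battery> %s: %d tests, mean recruitment VP %.6g / VMC %.6g\n",
              attr(x, "label") %||% "unnamed", nrow(x),
              mw$mean_vp, mw$mean_vmc))
  NextMethod()
}
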