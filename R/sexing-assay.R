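#' Call the sex of one sample from marker amplification and control status
#'
#' Decision rule for a PCR sexing assay built on Y-linked (male-specific)
#' markers plus a positive control: a failed control invalidates the sample
#' (\code{"failed"}); otherwise amplification of at least one male-linked
#' marker calls the sample male, and amplification of none calls it female.
#' When the male markers disagree the call is still male but a discordance
#' flag is raised, since individual Y-hemizygous markers can drop out. A
#' male whose markers all fail but whose control passes is (wrongly) called
#' female — such errors are only detectable against known-sex individuals,
#' via [validate_assay()].
#'
#' @param amplified Named logical/0-1 vector: amplification per male-linked
#'   marker.
#' @param control \code{"pass"} or \code{"fail"}.
#' @param markers Character vector of the known male-linked marker ids;
#'   names of \code{amplified} must all belong to it.
#' @return A list of class \code{sex_call}: \code{call} (\code{"male"},
#'   \code{"female"} or \code{"failed"}), \code{markers} (the evidence),
#'   \code{control}, \code{discordant}.
#' @examples
#' call_sex(c(Lm123977 = TRUE, Lm435135 = TRUE), "pass")
#' call_sex(c(Lm123977 = TRUE, Lm435135 = FALSE), "pass")  # male, discordant
#' @export
call_sex <- function(amplified, control = "pass",
                     markers = names(amplified)) {
  if (is.null(names(amplified)) || length(amplified) < 1L) {
    stop("`amplified` must be a named vector with >= 1 marker",
         call. = FALSE)
  }
  if (!all(names(amplified) %in% markers)) {
    stop("unknown marker id(s): ",
         paste(setdiff(names(amplified), markers), collapse = ", "),
         call. = FALSE)
  }
  if (!control %in% c("pass", "fail")) {
    stop('`control` must be "pass" or "fail"', call. = FALSE)
  }
  amp <- as.logical(amplified)
  call <- if (control == "fail") "failed"
          else if (any(amp)) "male" else "female"
  structure(list(call = call,
                 markers = stats::setNames(amp, names(amplified)),
                 control = control,
                 discordant = control == "pass" && any(amp) && !all(amp)),
            class = "sex_call")
}

#' @export
print.sex_call <- function(x, ...) {
  cat(sprintf("sex call: %s (control %s%s)\n", x$call, x$control,
              if (x$discordant) ", marker discordance" else ""))
  invisible(x)
}

#' Call sexes for a whole assay table
#'
#' Applies [call_sex()] to each individual in a long-format assay call
#' table, such as the one written by [simulate_assay_calls()].
#'
#' @param assay data.frame with columns \code{individual_id},
#'   \code{marker_id}, \code{amplified} (0/1) and \code{control}.
#' @param markers Known male-linked marker ids (default: those present).
#' @return data.frame with one row per individual: \code{individual_id},
#'   \code{call}, \code{control}, \code{discordant}, plus one
#'   \code{amp_<marker>} logical column per marker.
#' @export
call_sex_table <- function(assay, markers = NULL) {
  stopifnot(is.data.frame(assay),
            all(c("individual_id", "marker_id", "amplified", "control") %in%
                  names(assay)))
  if (is.null(markers)) markers <- sort(unique(assay$marker_id))
  ids <- unique(assay$individual_id)
  rows <- lapply(ids, function(id) {
    sub <- assay[assay$individual_id == id, ]
    amp <- stats::setNames(as.logical(sub$amplified), sub$marker_id)
    ctrl <- unique(sub$control)
    if (length(ctrl) != 1L) {
      stop(sprintf("inconsistent control status for %s", id), call. = FALSE)
    }
    sc <- call_sex(amp, ctrl, markers = markers)
    out <- data.frame(individual_id = id, call = sc$call,
                      control = sc$control, discordant = sc$discordant,
                      stringsAsFactors = FALSE)
    for (m in markers) out[[paste0("amp_", m)]] <- isTRUE(unname(amp[m]))
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Validate assay sex calls against known-sex individuals
#'
#' Compares assay calls with a registry of individuals of known sex and
#' summarises the assay's accuracy: how many known females amplified any
#' male marker (expected zero for truly Y-linked markers), how many known
#' males amplified each marker, how many known males were called female
#' (marker dropout), and how many samples failed their positive control.
#'
#' @param calls Output of [call_sex_table()].
#' @param known Registry data.frame with \code{individual_id} and
#'   \code{sex} (\code{"M"}/\code{"F"}); every called individual must
#'   appear.
#' @return A list of class \code{assay_validation}: \code{n_females},
#'   \code{n_males}, \code{false_male} (known females amplifying),
#'   \code{per_marker} (data.frame: marker, males amplifying, females
#'   amplifying), \code{males_called_female} (ids), \code{n_failed}.
#' @export
validate_assay <- function(calls, known) {
  stopifnot(is.data.frame(calls), is.data.frame(known),
            all(c("individual_id", "sex") %in% names(known)))
  sx <- known$sex[match(calls$individual_id, known$individual_id)]
  if (anyNA(sx)) {
    stop("individuals missing from the known-sex registry: ",
         paste(calls$individual_id[is.na(sx)], collapse = ", "),
         call. = FALSE)
  }
  amp_cols <- grep("^amp_", names(calls), value = TRUE)
  markers <- sub("^amp_", "", amp_cols)
  ok <- calls$call != "failed"
  is_f <- sx == "F" & ok
  is_m <- sx == "M" & ok

  any_amp <- if (length(amp_cols)) {
    Reduce(`|`, lapply(amp_cols, function(cc) calls[[cc]]))
  } else rep(FALSE, nrow(calls))

  per_marker <- data.frame(
    marker = markers,
    males_amplified = vapply(amp_cols, function(cc) sum(calls[[cc]] & is_m),
                             integer(1)),
    males_tested = sum(is_m),
    females_amplified = vapply(amp_cols,
                               function(cc) sum(calls[[cc]] & is_f),
                               integer(1)),
    females_tested = sum(is_f),
    stringsAsFactors = FALSE)
  rownames(per_marker) <- NULL

  structure(list(
    n_females = sum(is_f),
    n_males = sum(is_m),
    false_male = sum(is_f & any_amp),
    per_marker = per_marker,
    males_called_female = calls$individual_id[is_m & calls$call == "female"],
    n_failed = sum(calls$call == "failed")),
    class = "assay_validation")
}

#' @export
print.assay_validation <- function(x, ...) {
  cat(sprintf(
    "assay validation: %d known females, %d known males (controls passing)\n",
    x$n_females, x$n_males))
  cat(sprintf("  false-male calls (females amplifying): %d\n", x$false_male))
  cat(sprintf("  known males called female: %d\n",
              length(x$males_called_female)))
  cat(sprintf("  control failures: %d\n", x$n_failed))
  print(x$per_marker, row.names = FALSE)
  invisible(x)
}
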