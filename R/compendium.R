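# Activity catalog: behavior codes -> MET intensities for the 24-hour
# diary, plus the fixed intensity-class table used by the 7-day recall.

DIARY_CATEGORIES <- c("work", "commute", "leisure", "sports")

#' Construct an activity compendium
#'
#' A compendium binds short activity codes to MET (metabolic equivalent)
#' intensities, organised in the four diary categories: work-related
#' activities, way to work, leisure-time activities, and sports
#' activities.  The shipped default table (see [default_compendium()])
#' carries 66+ common adult behaviors with MET values taken from the
#' standard compendium of physical activities; any table with the same
#' columns can be supplied instead.
#'
#' @param activities data frame with columns `code`, `label`, `category`,
#'   `mets`.
#' @param version character tag recorded on the object.
#' @return An object of class `compendium` (a validated data frame).
#' @examples
#' cmp <- compendium(data.frame(
#'   code = c("sleep", "desk"), label = c("Sleeping", "Desk work"),
#'   category = c("leisure", "work"), mets = c(0.9, 1.5)))
#' lookup_mets(cmp, "sleep")
#' @export
compendium <- function(activities, version = "custom") {
  required <- c("code", "label", "category", "mets")
  missing_cols <- setdiff(required, names(activities))
  if (length(missing_cols))
    stop("compendium table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  activities <- as.data.frame(activities)[required]
  activities$code <- as.character(activities$code)
  activities$category <- as.character(activities$category)
  activities$mets <- as.numeric(activities$mets)
  if (anyDuplicated(activities$code))
    stop("duplicate activity codes: ",
         paste(unique(activities$code[duplicated(activities$code)]),
               collapse = ", "), call. = FALSE)
  bad_cat <- setdiff(unique(activities$category), DIARY_CATEGORIES)
  if (length(bad_cat))
    stop("categories must be one of ",
         paste(DIARY_CATEGORIES, collapse = "/"),
         "; found: ", paste(bad_cat, collapse = ", "), call. = FALSE)
  if (any(!is.finite(activities$mets) | activities$mets <= 0 |
          activities$mets > 20))
    stop("MET values must lie in (0, 20]", call. = FALSE)
  structure(activities, class = c("compendium", "data.frame"),
            version = version)
}

#' Read a compendium from CSV
#'
#' Expects a UTF-8 CSV with header `code,label,category,mets`.
#'
#' @param path path to the CSV file.
#' @param version character tag; defaults to the file name.
#' @return A `compendium` object.
#' @export
read_compendium_csv <- function(path, version = basename(path)) {
  if (!file.exists(path))
    stop("compendium file not found: ", path, call. = FALSE)
  compendium(utils::read.csv(path, stringsAsFactors = FALSE,
                             encoding = "UTF-8"),
             version = version)
}

#' The shipped default activity table
#'
#' 66+ behaviors across the four diary categories, including `sleep`
#' (0.9 METs) and `sitting_quietly` (1.1 METs, the sitting resting
#' metabolic rate reference).
#'
#' @return A `compendium` object.
#' @export
default_compendium <- function() {
  path <- system.file("extdata", "compendium_default.csv",
                      package = "paeeval", mustWork = TRUE)
  read_compendium_csv(path, version = "default")
}

#' Look up MET values by activity code
#'
#' @param compendium a `compendium` object.
#' @param code character vector of activity codes.
#' @return Numeric vector of MET values, one per code.
#' @examples
#' lookup_mets(default_compendium(), c("sleep", "jogging"))
#' @export
lookup_mets <- function(compendium, code) {
  stopifnot(inherits(compendium, "compendium"))
  idx <- match(code, compendium$code)
  if (anyNA(idx)) {
    unknown <- unique(code[is.na(idx)])
    stop("unknown activity code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  compendium$mets[idx]
}

#' @export
print.compendium <- function(x, ...) {
  cat("Activity compendium (", attr(x, "version"), "): ",
      nrow(x), " activities\n", sep = "")
  cat("  categories:", paste(sort(unique(x$category)), collapse = ", "), "\n")
  cat("  MET range: [", min(x$mets), ", ", max(x$mets), "]\n", sep = "")
  invisible(x)
}

#' The recall instrument's intensity-class table
#'
#' Seven classes with the fixed scoring METs used by the 7-day recall
#' (sleep 0.9, very light 1.3, light 2.2, moderate 3.5, moderate-to-high
#' 4.5, high 7.0, very high 10.0) and, where the instrument displays one,
#' the descriptive MET range presented to respondents (light 1.5-2.9,
#' moderate 3.0-3.9, moderate-to-high 4.0-5.9, high 6.0-7.9, very high
#' >= 8.0).  Sleep and very-light carry no selectable range: sleep is
#' reported directly in hours and very light is the fill for unaccounted
#' time.
#'
#' @return A data frame with columns `name`, `mets`, `range_low`,
#'   `range_high`.
#' @export
intensity_classes <- function() {
  data.frame(
    name       = c("sleep", "very_light", "light", "moderate",
                   "moderate_high", "high", "very_high"),
    mets       = c(0.9, 1.3, 2.2, 3.5, 4.5, 7.0, 10.0),
    range_low  = c(NA, NA, 1.5, 3.0, 4.0, 6.0, 8.0),
    range_high = c(NA, NA, 2.9, 3.9, 5.9, 7.9, Inf),
    stringsAsFactors = FALSE
  )
}

#' Map a MET value to its intensity class
#'
#' Classification is total over positive METs: the printed descriptive
#' ranges are closed at their endpoints and the narrow gaps between them
#' (2.9-3.0, 3.9-4.0, 5.9-6.0, 7.9-8.0) are resolved by extending each
#' range half-open up to the next one's lower bound, so 2.95 is light and
#' 3.0 is moderate.  Values below 1.5 METs fall in the sub-light region,
#' returned as `very_light` unless `asleep = TRUE` marks the time as
#' sleep.
#'
#' @param mets numeric vector of positive MET values.
#' @param asleep logical (recycled): classify sub-light time as sleep?
#' @return Character vector of class names from [intensity_classes()].
#' @examples
#' class_for_mets(c(3.5, 8.0, 2.9, 3.0, 1.0))
#' @export
class_for_mets <- function(mets, asleep = FALSE) {
  if (any(!is.finite(mets) | mets <= 0))
    stop("MET values must be positive and finite", call. = FALSE)
  asleep <- rep_len(asleep, length(mets))
  # half-open bins [1.5, 3.0), [3.0, 4.0), [4.0, 6.0), [6.0, 8.0), [8.0, Inf)
  cls <- as.character(cut(mets,
                          breaks = c(0, 1.5, 3.0, 4.0, 6.0, 8.0, Inf),
                          labels = c("sub_light", "light", "moderate",
                                     "moderate_high", "high", "very_high"),
                          right = FALSE))
  sub <- cls == "sub_light"
  cls[sub] <- ifelse(asleep[sub], "sleep", "very_light")
  cls
}

# scoring METs for a vector of class names
mets_for_class <- function(name) {
  tbl <- intensity_classes()
  idx <- match(name, tbl$name)
  if (anyNA(idx))
    stop("unknown intensity class(es): ",
         paste(unique(name[is.na(idx)]), collapse = ", "), call. = FALSE)
  tbl$mets[idx]
}
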