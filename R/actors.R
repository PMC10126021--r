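#' Read an actor table from a delimited text file
#'
#' Expects a header row with at least `id`, `gender` and `age`; any further
#' numeric columns are treated as trait scores. The field separator (comma
#' or tab) is auto-detected. Age is dichotomized into an `age_group` of
#' `"young"` (24 or younger) versus `"older"` (25 or older).
#'
#' @param path Path to the file.
#' @return A tibble with columns `actor_id`, `gender`, `age`, `age_group`
#'   and one column per trait.
#' @seealso [standardize_traits()] to impute and z-score the trait columns.
#' @export
read_actor_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("actor file not found: ", path))
  }
  raw <- read_delimited(path)
  need <- c("id", "gender", "age")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort(paste0("actor file misses column(s): ", paste(miss, collapse = ", ")))
  }
  ids <- as.character(raw$id)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    abort(paste0("duplicate actor id(s): ", paste(dup, collapse = ", ")))
  }
  gender <- tolower(as.character(raw$gender))
  bad <- which(!gender %in% c("male", "female"))
  if (length(bad)) {
    abort(paste0(
      "unknown gender level(s) in row(s) ", paste(bad, collapse = ", "),
      ": ", paste(unique(raw$gender[bad]), collapse = ", ")
    ))
  }
  age <- suppressWarnings(as.numeric(raw$age))
  if (anyNA(age)) {
    abort(paste0(
      "non-numeric age in row(s): ",
      paste(which(is.na(age)), collapse = ", ")
    ))
  }
  traits <- setdiff(names(raw), need)
  out <- tibble::tibble(
    actor_id = ids,
    gender = gender,
    age = age,
    age_group = ifelse(age <= 24, "young", "older")
  )
  for (tr in traits) {
    out[[tr]] <- suppressWarnings(as.numeric(raw[[tr]]))
  }
  out
}

#' Impute and standardize trait scores
#'
#' Missing trait values are replaced by the mean over the non-missing actors,
#' then each trait is z-scored (mean subtracted, divided by the sample
#' standard deviation over actors). The number of imputed values per trait is
#' recorded in the `"imputed"` attribute of the result.
#'
#' @param actors Actor table with numeric trait columns.
#' @param traits Character vector of trait column names; default: every
#'   numeric column other than `age`.
#' @return The actor table with standardized traits.
#' @examples
#' a <- tibble::tibble(
#'   actor_id = c("x", "y", "z"), gender = "female",
#'   age = 20, age_group = "young", extraversion = c(4, 6, NA)
#' )
#' standardize_traits(a)$extraversion # -1, 1, 0
#' @export
standardize_traits <- function(actors, traits = NULL) {
  if (is.null(traits)) {
    num <- vapply(actors, is.numeric, logical(1))
    traits <- setdiff(names(actors)[num], c("age"))
  }
  imputed <- integer(0)
  for (tr in traits) {
    x <- actors[[tr]]
    if (is.null(x)) {
      abort(paste0("trait column not found: ", tr))
    }
    na <- is.na(x)
    if (all(na)) {
      abort(paste0("trait '", tr, "' has no observed values"))
    }
    x[na] <- mean(x[!na])
    s <- sd(x)
    if (s == 0) {
      abort(paste0("trait '", tr, "' has zero standard deviation"))
    }
    actors[[tr]] <- (x - mean(x)) / s
    imputed[tr] <- sum(na)
  }
  attr(actors, "imputed") <- imputed
  actors
}

#' Write an actor table in the delimited dialect read_actor_table() expects
#'
#' @param actors Actor table (`actor_id`, `gender`, `age`, traits).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_actor_table <- function(actors, path) {
  cols <- c("actor_id", "gender", "age")
  traits <- setdiff(
    names(actors)[vapply(actors, is.numeric, logical(1))], "age"
  )
  out <- actors[c(cols, traits)]
  names(out)[1] <- "id"
  readr::write_csv(out, path)
  invisible(path)
}

read_delimited <- function(path) {
  first <- readLines(path, n = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
}
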