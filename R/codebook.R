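#' Covariate codebook
#'
#' A codebook declares, for every covariate entering the risk-factor model,
#' its kind (`continuous`, `binary`, `nominal`, or `ordinal`) and, for
#' non-continuous covariates, the ordered category labels. The first category
#' is always the reference level omitted during dummy expansion, so a
#' k-category covariate contributes one group of k-1 indicator columns to the
#' design matrix. Ordinal covariates are dummy-coded like nominal ones (no
#' score coding).
#'
#' @param entries list of entries built with [codebook_entry()].
#' @return an object of class `bll_codebook`.
#' @seealso [default_codebook()] for the 31-covariate questionnaire layout
#'   used by the synthetic survey generator.
#' @export
codebook <- function(entries) {
  stopifnot(is.list(entries), length(entries) > 0)
  nm <- vapply(entries, function(e) e$name, "")
  if (anyDuplicated(nm)) {
    stop_invalid("duplicate covariate names in codebook: %s",
                 paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  for (e in entries) {
    if (!e$kind %in% c("continuous", "binary", "nominal", "ordinal")) {
      stop_invalid("entry '%s': unknown kind '%s'", e$name, e$kind)
    }
    if (e$kind != "continuous") {
      if (length(e$categories) < 2) {
        stop_invalid("entry '%s': needs >= 2 categories", e$name)
      }
      if (e$kind == "binary" && length(e$categories) != 2) {
        stop_invalid("entry '%s': binary entries need exactly 2 categories",
                     e$name)
      }
      if (anyDuplicated(e$categories)) {
        stop_invalid("entry '%s': duplicate categories", e$name)
      }
    }
  }
  structure(list(entries = entries), class = "bll_codebook")
}

#' @param name covariate name.
#' @param kind one of `"continuous"`, `"binary"`, `"nominal"`, `"ordinal"`.
#' @param categories ordered character vector of category labels; the first
#'   is the reference level. Ignored for continuous covariates.
#' @rdname codebook
#' @export
codebook_entry <- function(name, kind, categories = NULL) {
  list(name = name, kind = kind,
       categories = if (kind == "continuous") NULL else as.character(categories))
}

#' @export
print.bll_codebook <- function(x, ...) {
  cat(sprintf("Covariate codebook: %d covariates, %d groups, %d design columns\n",
              length(x$entries), length(x$entries), sum(codebook_df(x))))
  kinds <- vapply(x$entries, function(e) e$kind, "")
  for (k in unique(kinds)) {
    cat(sprintf("  %-10s %d\n", k, sum(kinds == k)))
  }
  invisible(x)
}

covariate_names <- function(cb) vapply(cb$entries, function(e) e$name, "")

# per-covariate dummy-column count (group degrees of freedom)
codebook_df <- function(cb) {
  vapply(cb$entries, function(e) {
    if (e$kind == "continuous") 1L else length(e$categories) - 1L
  }, 1L)
}

codebook_get <- function(cb, name) {
  for (e in cb$entries) if (e$name == name) return(e)
  stop_invalid("covariate '%s' not in codebook", name)
}

#' Default questionnaire codebook
#'
#' The default layout mirrors a lifestyle and residential-environment
#' questionnaire for kindergarten-age children: 4 continuous anthropometrics
#' (height, weight, head and chest circumference), the child's sex, an age
#' group, proximity of e-waste recycling workshops to the house, and 24
#' coded lifestyle/diet/household items. The 31 covariates expand to 72
#' dummy columns in 31 groups.
#'
#' @return a `bll_codebook` with 31 entries.
#' @export
default_codebook <- function() {
  freq4 <- c("no", "occasionally", "often", "always")
  entries <- c(
    list(
      codebook_entry("height", "continuous"),
      codebook_entry("weight", "continuous"),
      codebook_entry("head_circumference", "continuous"),
      codebook_entry("chest_circumference", "continuous"),
      codebook_entry("sex", "binary", c("boy", "girl")),
      codebook_entry("ewaste_proximity", "binary", c("no", "yes")),
      codebook_entry("age_group", "ordinal", c("under3", "a3to6", "over6"))
    ),
    lapply(c("wash_hands", "hand_to_mouth", "preserved_eggs", "dairy_products",
             "canned_food", "bean_products", "calcium_supplement",
             "toy_mouthing", "street_food", "nail_biting", "ewaste_contact"),
           codebook_entry, kind = "ordinal", categories = freq4),
    list(
      codebook_entry("household_income", "ordinal",
                     c("under_1000", "y1000_1500", "y1500_2000", "over_2000")),
      codebook_entry("mother_education", "ordinal",
                     c("primary", "middle", "high", "college")),
      codebook_entry("father_education", "ordinal",
                     c("primary", "middle", "high", "college")),
      codebook_entry("distance_to_road", "ordinal",
                     c("under_10m", "m10_50", "m50_100", "over_100m")),
      codebook_entry("household_smoking", "ordinal",
                     c("none", "light", "moderate", "heavy"))
    ),
    list(
      codebook_entry("outdoor_play", "ordinal", c("h0_1", "h1_3", "h3_plus")),
      codebook_entry("water_source", "nominal", c("tap", "well", "bottled")),
      codebook_entry("residence_years", "ordinal", c("under_2", "y2_5", "over_5")),
      codebook_entry("house_renovation", "ordinal",
                     c("none", "over_1y_ago", "within_1y")),
      codebook_entry("floor_dust", "ordinal", c("low", "medium", "high")),
      codebook_entry("vegetable_source", "nominal", c("market", "home_grown", "mixed")),
      codebook_entry("parent_ewaste_job", "ordinal", c("no", "part_time", "full_time")),
      codebook_entry("crowding", "ordinal", c("low", "medium", "high"))
    )
  )
  codebook(entries)
}

#' Read or write a codebook as JSON
#'
#' @param path file path.
#' @return `read_codebook()` returns a `bll_codebook`; `write_codebook()`
#'   returns `path` invisibly.
#' @export
read_codebook <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  codebook(lapply(raw, function(e) {
    codebook_entry(e$name, e$kind, unlist(e$categories))
  }))
}

#' @param cb a `bll_codebook`.
#' @rdname read_codebook
#' @export
write_codebook <- function(cb, path) {
  jsonlite::write_json(cb$entries, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}
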