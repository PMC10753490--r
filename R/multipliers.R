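#' Activity vocabulary
#'
#' The four behavioural categories used throughout the package: `flight`,
#' `forage`, `on_water` (resting/loafing on the sea surface) and `on_land`.
#' Every multiplier record, activity budget column and cost decomposition uses
#' exactly these labels.
#'
#' @return Character vector of the four activity kinds, in canonical order.
#' @export
#' @examples
#' activity_kinds()
activity_kinds <- function() {
  c("flight", "forage", "on_water", "on_land")
}

teb_data_file <- function(name) {
  path <- system.file("extdata", name, package = "seabirdTEB")
  if (!nzchar(path) || !file.exists(path)) {
    stop("packaged data file '", name, "' is missing or the package is corrupt",
         call. = FALSE)
  }
  path
}

read_teb_csv <- function(name) {
  path <- teb_data_file(name)
  out <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE),
    error = function(e) {
      stop("failed to read packaged data file '", name, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  out
}

# canonical key for case/whitespace-insensitive family matching
# ("procellariidaeC", "Procellariidae c " and "Procellariidae C" all match)
family_key <- function(x) {
  tolower(gsub("[[:space:]]+", "", x))
}

#' Load the packaged activity-specific BMR multiplier table
#'
#' Reads the collated table of activity-specific basal metabolic rate (BMR)
#' multipliers for nine measured marine bird families, the nine-guild taxonomy
#' of all 18 family-groups (the 16 marine bird families with Procellariidae
#' split into groups A/B/C), and the borrow rules through which data-deficient
#' families inherit multipliers from a measured donor family.
#'
#' Multipliers are dimensionless multiples of BMR: an activity with multiplier
#' `m` performed for `t` hours costs `t * BMR * m` kJ, with BMR in kJ h^-1.
#' Each record carries a provenance flag (`printed` for values printed in the
#' source collation, `reconstructed` for values re-derived from the primary
#' activity-cost literature) and a free-text source note.
#'
#' @return An object of class `multiplier_table`: a list with data frames
#'   `multipliers`, `families`, `guilds` and `borrow_rules`.
#' @export
#' @examples
#' tab <- load_multiplier_table()
#' subset(tab$multipliers, family_group == "Alcidae")
load_multiplier_table <- function() {
  mult <- read_teb_csv("bmr_multipliers.csv")
  fams <- read_teb_csv("family_guilds.csv")
  guilds <- read_teb_csv("guilds.csv")
  borrow <- read_teb_csv("borrow_rules.csv")

  tab <- structure(
    list(multipliers = mult, families = fams, guilds = guilds,
         borrow_rules = borrow),
    class = "multiplier_table"
  )
  validate_multiplier_table(tab)
  tab
}

validate_multiplier_table <- function(tab) {
  mult <- tab$multipliers
  fams <- tab$families
  guilds <- tab$guilds
  borrow <- tab$borrow_rules

  if (nrow(fams) != 18L) {
    stop("packaged family table must contain 18 family-groups, found ",
         nrow(fams), call. = FALSE)
  }
  if (nrow(guilds) != 9L || anyDuplicated(guilds$guild_id)) {
    stop("packaged guild table must contain 9 distinct guilds", call. = FALSE)
  }
  combo <- with(guilds, paste(flight_style, foraging_style,
                              rests_on_water, rests_on_land))
  if (anyDuplicated(combo)) {
    stop("guilds must be unique combinations of style fields", call. = FALSE)
  }
  if (sum(fams$has_direct_multipliers) != 9L) {
    stop("exactly 9 family-groups must carry direct multipliers", call. = FALSE)
  }
  if (!all(fams$guild_id %in% guilds$guild_id)) {
    stop("family table references unknown guild ids", call. = FALSE)
  }
  if (!all(mult$activity %in% activity_kinds()) ||
      !all(borrow$activity %in% activity_kinds())) {
    stop("multiplier records use unknown activity labels", call. = FALSE)
  }
  if (any(!is.finite(mult$multiplier)) || any(mult$multiplier <= 0)) {
    stop("all multipliers must be finite and > 0", call. = FALSE)
  }
  measured <- fams$family_group[fams$has_direct_multipliers]
  if (!all(mult$family_group %in% measured)) {
    stop("direct multiplier records exist for unmeasured families", call. = FALSE)
  }
  if (!all(borrow$donor_family %in% measured)) {
    stop("borrow rules must resolve to a measured family", call. = FALSE)
  }
  # every measured family covers at least the activities its guild performs
  for (f in measured) {
    g <- guilds[guilds$guild_id == fams$guild_id[fams$family_group == f], ]
    need <- performable_activities(g)
    have <- mult$activity[mult$family_group == f]
    if (!all(need %in% have)) {
      stop("measured family '", f, "' lacks multipliers for: ",
           paste(setdiff(need, have), collapse = ", "), call. = FALSE)
    }
  }
  invisible(tab)
}

#' @export
print.multiplier_table <- function(x, ...) {
  cat("Marine bird BMR multiplier table\n")
  cat("  ", nrow(x$families), "family-groups in", nrow(x$guilds), "guilds;",
      sum(x$families$has_direct_multipliers), "with direct multipliers\n")
  cat("  ", nrow(x$multipliers), "direct records,",
      nrow(x$borrow_rules), "borrow rules\n")
  invisible(x)
}

match_family <- function(family_group, tab) {
  key <- family_key(family_group)
  idx <- match(key, family_key(tab$families$family_group))
  if (is.na(idx)) {
    stop("unknown family-group '", family_group, "'; valid labels: ",
         paste(tab$families$family_group, collapse = ", "), call. = FALSE)
  }
  tab$families$family_group[idx]
}

#' Ecological guild of a family-group
#'
#' Returns the guild record (flight style, foraging style, resting substrates)
#' that a marine bird family-group belongs to. Family matching is case- and
#' whitespace-insensitive.
#'
#' @param family_group One of the 18 packaged family-group labels (e.g.
#'   `"Alcidae"`, `"Procellariidae C"`).
#' @param table A `multiplier_table`, by default the packaged one.
#' @return A one-row data frame with columns `guild_id`, `flight_style`,
#'   `foraging_style`, `rests_on_water`, `rests_on_land`.
#' @export
#' @examples
#' guild_of("Alcidae")
guild_of <- function(family_group, table = load_multiplier_table()) {
  fam <- match_family(family_group, table)
  gid <- table$families$guild_id[table$families$family_group == fam]
  g <- table$guilds[table$guilds$guild_id == gid, , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Activities a guild performs
#'
#' All guilds forage; flight is performed unless the guild is flightless;
#' `on_water` and `on_land` are performed according to the guild's resting
#' substrates.
#'
#' @param guild A one-row guild data frame as returned by [guild_of()].
#' @return Character vector, a subset of [activity_kinds()].
#' @export
performable_activities <- function(guild) {
  acts <- character()
  if (guild$flight_style != "flightless") acts <- c(acts, "flight")
  acts <- c(acts, "forage")
  if (isTRUE(guild$rests_on_water) || identical(guild$rests_on_water, "TRUE")) {
    acts <- c(acts, "on_water")
  }
  if (isTRUE(guild$rests_on_land) || identical(guild$rests_on_land, "TRUE")) {
    acts <- c(acts, "on_land")
  }
  acts
}

#' Resolve activity-specific BMR multipliers for a family-group
#'
#' For a measured family this returns its direct multipliers. For a
#' data-deficient family the packaged borrow rules are applied: each activity's
#' multiplier is taken from an explicitly recorded donor family (by default the
#' measured family sharing the same ecological guild). The mapping covers
#' exactly the activities the family's guild performs; activities the guild
#' never performs (e.g. flight for a flightless guild) are absent.
#'
#' @inheritParams guild_of
#' @return Named numeric vector of multipliers (names are activity kinds), with
#'   attribute `donor`: a named character vector giving, per activity, the
#'   family whose measurement supplied the value.
#' @export
#' @examples
#' resolve_multipliers("Diomedeidae")
#' resolve_multipliers("Procellariidae C")   # borrowed from donors
resolve_multipliers <- function(family_group, table = load_multiplier_table()) {
  fam <- match_family(family_group, table)
  guild <- guild_of(fam, table)
  acts <- performable_activities(guild)
  measured <- table$families$has_direct_multipliers[
    table$families$family_group == fam]

  vals <- stats::setNames(numeric(length(acts)), acts)
  donor <- stats::setNames(character(length(acts)), acts)
  for (a in acts) {
    if (measured) {
      src <- fam
    } else {
      rule <- table$borrow_rules[
        family_key(table$borrow_rules$family_group) == family_key(fam) &
          table$borrow_rules$activity == a, , drop = FALSE]
      if (nrow(rule) == 0L) {
        stop("no donor recorded for '", fam, "' activity '", a,
             "'; refusing to default silently", call. = FALSE)
      }
      src <- rule$donor_family[1L]
    }
    rec <- table$multipliers[
      table$multipliers$family_group == src &
        table$multipliers$activity == a, , drop = FALSE]
    if (nrow(rec) == 0L) {
      stop("no multiplier available for '", fam, "' activity '", a,
           "' (donor '", src, "' has no record)", call. = FALSE)
    }
    vals[a] <- rec$multiplier[1L]
    donor[a] <- src
  }
  attr(vals, "donor") <- donor
  vals
}
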