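# Hunting-season bookkeeping. Drive hunts - the only hunting mode that
# targets resting animals in the study system - are open from mid-August to
# late winter and permitted only on fixed weekdays plus bank holidays.

#' Define a drive-hunt calendar
#'
#' @param open_md,close_md Month-day strings ("MM-DD"). The open season runs
#'   from `open_md` of one year through `close_md` of the next (default
#'   15 Aug - 31 Mar).
#' @param hunting_weekdays Integer ISO weekdays on which driven hunts are
#'   permitted (1 = Monday ... 7 = Sunday; default Wed/Sat/Sun).
#' @param holidays `Date` vector of bank holidays (also hunting days when
#'   they fall inside the open season).
#' @return An object of class `hunting_calendar`.
#' @export
hunting_calendar <- function(open_md = "08-15", close_md = "03-31",
                             hunting_weekdays = c(3L, 6L, 7L),
                             holidays = as.Date(character())) {
  stopifnot(length(hunting_weekdays) > 0)
  structure(list(open_md = open_md, close_md = close_md,
                 hunting_weekdays = as.integer(hunting_weekdays),
                 holidays = as.Date(holidays)),
            class = "hunting_calendar")
}

#' Label dates by hunting-season status
#'
#' Three levels: `NHS` (closed season), `HS_nonhunting` (open season,
#' no driven hunts that day) and `HS_hunting_day` (open season, permitted
#' weekday or bank holiday).
#'
#' @param date `Date` vector.
#' @param calendar A [hunting_calendar()].
#' @return Factor with levels `NHS`, `HS_nonhunting`, `HS_hunting_day`.
#' @export
season_label <- function(date, calendar = hunting_calendar()) {
  md <- format(date, "%m-%d")
  in_season <- md >= calendar$open_md | md <= calendar$close_md
  wd <- as.integer(format(date, "%u"))
  hunting <- wd %in% calendar$hunting_weekdays | date %in% calendar$holidays
  out <- ifelse(!in_season, "NHS",
                ifelse(hunting, "HS_hunting_day", "HS_nonhunting"))
  factor(out, levels = c("NHS", "HS_nonhunting", "HS_hunting_day"))
}

#' Collapse the 3-level season label to NHS/HS
#' @param season3 Factor from [season_label()].
#' @return Factor with levels `NHS`, `HS`.
#' @export
season2 <- function(season3) {
  factor(ifelse(season3 == "NHS", "NHS", "HS"), levels = c("NHS", "HS"))
}
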