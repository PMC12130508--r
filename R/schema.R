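#' The fixed 9-channel schema of an in-air signature
#'
#' Every in-air signature carries nine channels in a fixed order: three axes
#' each from the accelerometer (`acc_x`, `acc_y`, `acc_z`, in m/s^2), the
#' gyroscope (`gyr_x`, `gyr_y`, `gyr_z`) and the attitude sensor (`att_x` =
#' pitch, `att_y` = roll, `att_z` = yaw; radians assumed — the capture
#' pipeline only documents units for the accelerometer).
#'
#' @return An object of class `channel_schema`: a list with `names` (ordered
#'   channel labels), `sensor_of` and `axis_of` (named character vectors
#'   mapping channel to sensor and axis).
#' @examples
#' channel_schema()$names
#' @export
channel_schema <- function() {
  names <- c(
    "acc_x", "acc_y", "acc_z",
    "gyr_x", "gyr_y", "gyr_z",
    "att_x", "att_y", "att_z"
  )
  sensor <- setNames(
    rep(c("accelerometer", "gyroscope", "attitude"), each = 3L),
    names
  )
  axis <- setNames(
    c("x", "y", "z", "x", "y", "z", "pitch", "roll", "yaw"),
    names
  )
  structure(
    list(names = names, sensor_of = sensor, axis_of = axis),
    class = "channel_schema"
  )
}

#' @export
print.channel_schema <- function(x, ...) {
  cat("<channel_schema> 9 channels:", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

# Accepted header spellings, normalized to the canonical abbreviations.
# Both `acc_x`/`Acc_x` and the `Ori_*` spelling of the attitude channels
# occur in the wild.
normalize_channel_names <- function(nms) {
  canon <- tolower(trimws(nms))
  canon <- sub("^ori_", "att_", canon)
  schema <- channel_schema()$names
  bad <- setdiff(canon, schema)
  if (length(bad) > 0L) {
    abort_airsig(
      sprintf(
        "Unrecognised channel column(s): %s. Expected the 9 channels %s (Ori_* accepted for att_*).",
        paste(sQuote(nms[canon %in% bad]), collapse = ", "),
        paste(schema, collapse = ", ")
      ),
      "airsig_schema_error"
    )
  }
  if (anyDuplicated(canon) || length(canon) != 9L) {
    abort_airsig(
      "Header must contain each of the 9 channel columns exactly once.",
      "airsig_schema_error"
    )
  }
  canon
}

DEVICES <- c("phone", "smartwatch")

check_device <- function(device) {
  if (!is.character(device) || length(device) != 1L || !(device %in% DEVICES)) {
    abort_airsig(
      sprintf("`device` must be one of %s.", paste(sQuote(DEVICES), collapse = ", ")),
      "airsig_config_error"
    )
  }
  device
}
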