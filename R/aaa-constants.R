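# Shared constants (defined first in the collation order).

# standard gravity (m/s^2)
GRAVITY <- 9.81

ANGLE_CHANNELS <- c("left_hip", "left_knee", "left_ankle",
                    "right_hip", "right_knee", "right_ankle")

# Gamma-shaped impact bump: zero (with zero slope) at foot contact, unit
# peak at t = t_p, fast decay; smooth everywhere, so the 20 N threshold is
# not tripped ahead of contact.
PASSIVE_BUMP_SHAPE <- 2
passive_bump <- function(u) {
  out <- numeric(length(u))
  pos <- u > 0
  out[pos] <- (u[pos] * exp(1 - u[pos]))^PASSIVE_BUMP_SHAPE
  out
}
# integral of passive_bump over u >= 0:
# e^k * Gamma(k+1) / k^(k+1), k = PASSIVE_BUMP_SHAPE
PASSIVE_BUMP_AREA <- exp(PASSIVE_BUMP_SHAPE) * gamma(PASSIVE_BUMP_SHAPE + 1) /
  PASSIVE_BUMP_SHAPE^(PASSIVE_BUMP_SHAPE + 1)

N_FOURIER <- 16L
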