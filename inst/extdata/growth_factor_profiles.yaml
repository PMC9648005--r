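# Growth-factor clamp profiles for canalization under imposed environments.
# Profile A emulates a normal healthy environment, profile B a pathological
# one; both fix seven growth factors while every other variable is
# initialized at random. The published numeric values are embedded in a
# figure table that is not distributed with this package: the placeholders
# below MUST be replaced by transcribed values before profile experiments on
# the full model are meaningful. (For the shipped toy fixtures these
# profiles are not used.)
profile_A:
  # e.g. TGFB: 1.0, IGF: 1.0, WNT: 0.0, ... -- transcribe from the source
  {}
profile_B:
  {}
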