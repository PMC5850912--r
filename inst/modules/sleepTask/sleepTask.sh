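#!/bin/sh
set -eu
WAIT=0
while [ $# -gt 0 ]; do case "$1" in
  --wait) WAIT="$2"; shift 2 ;;
  *) echo "unknown arg $1" >&2; exit 64 ;;
esac; done
sleep "$WAIT"
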