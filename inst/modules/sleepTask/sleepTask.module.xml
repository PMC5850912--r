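<module name="sleepTask" command="sleepTask.sh">
  <param name="wait" type="integer" required="true" min="0"/>
</module>
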