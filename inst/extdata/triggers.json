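["年", "月", "日", "号", "周", "星期", "天", "小时", "时", "点", "分", "秒",
 "次", "每", "前", "后", "第"]
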