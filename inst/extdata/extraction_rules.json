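[
  {"rule_id": "datetime_cn", "family": "CLOCK_TIME",
   "pattern": "[0-9]{4}年[0-9]{1,2}月[0-9]{1,2}日\\s*(?:上午|下午|凌晨|晚)?\\s*[0-9]{1,2}[点时][0-9]{1,2}分(?:[0-9]{1,2}秒)?"},
  {"rule_id": "datetime_slash", "family": "CLOCK_TIME",
   "pattern": "[0-9]{4}[/-][0-9]{1,2}[/-][0-9]{1,2}[ T][0-9]{1,2}:[0-9]{2}(?::[0-9]{2})?"},
  {"rule_id": "clock_cn", "family": "CLOCK_TIME",
   "pattern": "(?:上午|下午|凌晨|晚)[0-9]{1,2}[点时](?:[0-9]{1,2}分(?:[0-9]{1,2}秒)?)?"},
  {"rule_id": "clock_colon", "family": "CLOCK_TIME",
   "pattern": "[0-9]{1,2}:[0-9]{2}(?::[0-9]{2})?"},
  {"rule_id": "date_cn", "family": "ABSOLUTE_DATE",
   "pattern": "[0-9]{4}年(?:[0-9]{1,2}月(?:[0-9]{1,2}日)?)?"},
  {"rule_id": "date_dash", "family": "ABSOLUTE_DATE",
   "pattern": "[0-9]{4}-[0-9]{1,2}(?:-[0-9]{1,2})?"},
  {"rule_id": "date_slash", "family": "ABSOLUTE_DATE",
   "pattern": "[0-9]{4}/[0-9]{1,2}/[0-9]{1,2}"},
  {"rule_id": "date_day_month", "family": "ABSOLUTE_DATE",
   "pattern": "[0-9]{1,2}/[0-9]{1,2}"},
  {"rule_id": "month_ref", "family": "RELATIVE",
   "pattern": "[0-9]{1,2}月(?:[0-9]{1,2}日)?"},
  {"rule_id": "relative", "family": "RELATIVE",
   "pattern": "(?:[0-9]+|[一二三四五六七八九十两零]+)\\s*(?:个月|个小时|小时|分钟|星期|年|月|周|天|日|时|秒)\\s*[余约多]?\\s*[前后]"},
  {"rule_id": "duration_compound", "family": "DURATION",
   "pattern": "(?:[0-9]+|[一二三四五六七八九十两零]+)年(?:[0-9]+|[一二三四五六七八九十两零]+)个月"},
  {"rule_id": "duration", "family": "DURATION",
   "pattern": "(?:[0-9]+|[一二三四五六七八九十两零]+)\\s*(?:个月|个小时|小时|分钟|星期|年|周|天|日|秒)(?:[余约多](?=[,，。;；!?！？\\n]|$))?"},
  {"rule_id": "set_days", "family": "SET",
   "pattern": "第(?:[0-9]+|[一二三四五六七八九十两零]+)(?:[、,，](?:[0-9]+|[一二三四五六七八九十两零]+))*天"},
  {"rule_id": "deictic_muqian", "family": "DEICTIC", "pattern": "目前"},
  {"rule_id": "deictic_xianzai", "family": "DEICTIC", "pattern": "现在"},
  {"rule_id": "deictic_jintian", "family": "DEICTIC", "pattern": "今天|今晨|今日"},
  {"rule_id": "deictic_admission", "family": "DEICTIC", "pattern": "入院时"},
  {"rule_id": "deictic_discharge", "family": "DEICTIC", "pattern": "出院时"},
  {"rule_id": "deictic_xian", "family": "DEICTIC", "pattern": "(?<![发出呈表实])现(?![象])"}
]
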