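c SYNTHETIC stand-in for the 193-country world border graph:
c a seeded planar triangulated-grid graph of the same order.
p edge 193 526
e 1 2
e 1 13
e 1 14
e 1 15
e 2 3
e 2 15
e 2 16
e 3 4
e 3 16
e 3 17
e 4 5
e 4 17
e 4 18
e 5 6
e 5 18
e 6 7
e 6 18
e 6 19
e 7 8
e 7 19
e 7 20
e 8 9
e 8 20
e 8 21
e 9 10
e 9 21
e 9 22
e 9 23
e 10 11
e 10 23
e 10 24
e 11 12
e 11 24
e 11 25
e 12 25
e 13 14
e 13 27
e 14 15
e 14 27
e 14 28
e 15 16
e 15 28
e 15 29
e 15 30
e 16 17
e 16 30
e 16 31
e 17 18
e 17 31
e 18 19
e 18 31
e 18 32
e 19 20
e 19 32
e 19 33
e 20 21
e 20 33
e 20 34
e 21 22
e 21 34
e 21 35
e 22 23
e 22 35
e 22 36
e 23 24
e 23 36
e 23 37
e 24 25
e 24 37
e 24 38
e 25 26
e 25 38
e 25 39
e 25 40
e 26 40
e 27 28
e 27 41
e 27 42
e 28 29
e 28 42
e 28 43
e 29 30
e 29 43
e 30 31
e 30 43
e 30 44
e 31 32
e 31 44
e 31 45
e 31 46
e 32 33
e 32 46
e 32 47
e 33 34
e 33 47
e 34 35
e 34 47
e 34 48
e 34 49
e 35 36
e 35 49
e 35 50
e 36 37
e 36 50
e 36 51
e 37 38
e 37 51
e 38 39
e 38 51
e 38 52
e 38 53
e 39 40
e 39 53
e 39 54
e 40 54
e 41 42
e 41 55
e 41 56
e 42 43
e 42 56
e 42 57
e 43 44
e 43 57
e 44 45
e 44 57
e 44 58
e 45 46
e 45 58
e 45 59
e 45 60
e 46 47
e 46 60
e 47 48
e 47 60
e 47 61
e 47 62
e 48 49
e 48 62
e 48 63
e 49 50
e 49 63
e 50 51
e 50 63
e 50 64
e 51 52
e 51 64
e 51 65
e 51 66
e 52 53
e 52 66
e 53 54
e 53 66
e 53 67
e 53 68
e 54 68
e 55 56
e 55 69
e 55 70
e 56 57
e 56 70
e 57 58
e 57 70
e 57 71
e 57 72
e 58 59
e 58 72
e 58 73
e 59 60
e 59 73
e 60 61
e 60 73
e 60 74
e 61 62
e 61 74
e 61 75
e 62 63
e 62 75
e 62 76
e 62 77
e 63 64
e 63 77
e 63 78
e 64 65
e 64 78
e 64 79
e 65 66
e 65 79
e 65 80
e 66 67
e 66 80
e 66 81
e 67 68
e 67 81
e 67 82
e 68 82
e 69 70
e 69 83
e 69 84
e 70 71
e 70 84
e 70 85
e 71 72
e 71 85
e 71 86
e 72 73
e 72 86
e 73 74
e 73 86
e 73 87
e 74 75
e 74 87
e 74 88
e 74 89
e 75 76
e 75 89
e 75 90
e 76 77
e 76 90
e 77 78
e 77 90
e 77 91
e 78 79
e 78 91
e 78 92
e 79 80
e 79 92
e 79 93
e 79 94
e 80 81
e 80 94
e 81 82
e 81 94
e 81 95
e 81 96
e 82 96
e 83 84
e 83 97
e 83 98
e 84 85
e 84 98
e 84 99
e 85 86
e 85 99
e 86 87
e 86 99
e 86 100
e 86 101
e 87 88
e 87 101
e 87 102
e 88 89
e 88 102
e 89 90
e 89 102
e 89 103
e 89 104
e 90 91
e 90 104
e 90 105
e 91 92
e 91 105
e 91 106
e 92 93
e 92 106
e 92 107
e 93 94
e 93 107
e 93 108
e 94 95
e 94 108
e 94 109
e 95 96
e 95 109
e 96 109
e 96 110
e 97 98
e 97 111
e 98 99
e 98 111
e 98 112
e 98 113
e 99 100
e 99 113
e 100 101
e 100 113
e 100 114
e 100 115
e 101 102
e 101 115
e 102 103
e 102 115
e 102 116
e 102 117
e 103 104
e 103 117
e 103 118
e 104 105
e 104 118
e 104 119
e 105 106
e 105 119
e 105 120
e 106 107
e 106 120
e 106 121
e 107 108
e 107 121
e 107 122
e 108 109
e 108 122
e 108 123
e 109 110
e 109 123
e 109 124
e 110 124
e 111 112
e 111 125
e 112 113
e 112 125
e 112 126
e 113 114
e 113 126
e 113 127
e 114 115
e 114 127
e 114 128
e 114 129
e 115 116
e 115 129
e 115 130
e 116 117
e 116 130
e 116 131
e 117 118
e 117 131
e 118 119
e 118 131
e 118 132
e 118 133
e 119 120
e 119 133
e 119 134
e 120 121
e 120 134
e 121 122
e 121 134
e 121 135
e 122 123
e 122 135
e 122 136
e 123 124
e 123 136
e 123 137
e 124 137
e 124 138
e 125 126
e 125 139
e 125 140
e 126 127
e 126 140
e 126 141
e 127 128
e 127 141
e 128 129
e 128 141
e 128 142
e 128 143
e 129 130
e 129 143
e 129 144
e 130 131
e 130 144
e 130 145
e 131 132
e 131 145
e 131 146
e 132 133
e 132 146
e 132 147
e 133 134
e 133 147
e 134 135
e 134 147
e 134 148
e 134 149
e 135 136
e 135 149
e 135 150
e 136 137
e 136 150
e 136 151
e 137 138
e 137 151
e 138 151
e 138 152
e 139 140
e 139 153
e 139 154
e 140 141
e 140 154
e 140 155
e 141 142
e 141 155
e 142 143
e 142 155
e 142 156
e 142 157
e 143 144
e 143 157
e 144 145
e 144 157
e 144 158
e 144 159
e 145 146
e 145 159
e 146 147
e 146 159
e 146 160
e 147 148
e 147 160
e 147 161
e 147 162
e 148 149
e 148 162
e 149 150
e 149 162
e 149 163
e 149 164
e 150 151
e 150 164
e 150 165
e 151 152
e 151 165
e 151 166
e 152 166
e 153 154
e 153 167
e 153 168
e 154 155
e 154 168
e 154 169
e 155 156
e 155 169
e 155 170
e 156 157
e 156 170
e 156 171
e 157 158
e 157 171
e 158 159
e 158 171
e 158 172
e 158 173
e 159 160
e 159 173
e 160 161
e 160 173
e 160 174
e 160 175
e 161 162
e 161 175
e 161 176
e 162 163
e 162 176
e 163 164
e 163 176
e 163 177
e 164 165
e 164 177
e 164 178
e 164 179
e 165 166
e 165 179
e 166 179
e 166 180
e 167 168
e 167 181
e 168 169
e 168 181
e 169 170
e 169 181
e 169 182
e 169 183
e 170 171
e 170 183
e 170 184
e 171 172
e 171 184
e 172 173
e 172 184
e 172 185
e 172 186
e 173 174
e 173 186
e 174 175
e 174 186
e 174 187
e 174 188
e 175 176
e 175 188
e 176 177
e 176 188
e 176 189
e 176 190
e 177 178
e 177 190
e 177 191
e 178 179
e 178 191
e 178 192
e 179 180
e 179 192
e 179 193
e 180 193
e 181 182
e 182 183
e 183 184
e 184 185
e 185 186
e 186 187
e 187 188
e 188 189
e 189 190
e 190 191
e 191 192
e 192 193
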